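#' Construct a probe annotation table
#'
#' The probe annotation maps every probe on the panel to its code class
#' (Endogenous, Housekeeping, Positive, Negative), its pathway memberships,
#' its cell-type marker assignments, and -- for positive controls -- the
#' spike-in concentration of the titration series.
#'
#' @param gene_id Character vector of unique probe names.
#' @param code_class Character vector, one of `"Endogenous"`, `"Housekeeping"`,
#'   `"Positive"`, `"Negative"`.
#' @param concentration Numeric vector of fM concentrations; `NA` except for
#'   Positive probes, which must carry a strictly positive value.
#' @param pathways List of character vectors: pathway names per probe.
#' @param celltypes List of character vectors: cell-type names per probe.
#' @return A `data.frame` of class `probe_annotation` with list-columns
#'   `pathways` and `celltypes`.
#' @export
probe_annotation <- function(gene_id, code_class,
                             concentration = rep(NA_real_, length(gene_id)),
                             pathways = rep(list(character()), length(gene_id)),
                             celltypes = rep(list(character()), length(gene_id))) {
  if (length(gene_id)) {
    code_class <- match.arg(code_class,
                            c("Endogenous", "Housekeeping", "Positive",
                              "Negative"), several.ok = TRUE)
  } else {
    code_class <- character()
  }
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in probe annotation: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (length(code_class) != length(gene_id))
    code_class <- rep(code_class, length.out = length(gene_id))
  pos <- code_class == "Positive"
  if (any(pos & (is.na(concentration) | concentration <= 0)))
    stop("Positive probes must carry a strictly positive concentration")
  if (any(code_class == "Negative" & !is.na(concentration)))
    stop("Negative probes must not carry a concentration")
  ann <- data.frame(gene_id = as.character(gene_id),
                    code_class = code_class,
                    concentration = as.numeric(concentration),
                    stringsAsFactors = FALSE)
  ann$pathways <- pathways
  ann$celltypes <- celltypes
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Read a lane-level RCC count file
#'
#' Parses the RCC dialect used by nCounter-style instruments: bracketed
#' sections (`<Header>`, `<Sample_Attributes>`, `<Lane_Attributes>`,
#' `<Code_Summary>`) holding comma-separated records. The `Code_Summary`
#' section carries one `CodeClass,Name,Accession,Count` row per probe;
#' `Lane_Attributes` carries the imaging fields-of-view counts and the
#' binding density.
#'
#' @param path Path to an RCC file (LF or CRLF line endings).
#' @return A `sample_lane` object: a list with `sample_id`, integer vector
#'   `counts` (named by probe), `fov_counted_pct` (percent of attempted
#'   fields of view successfully counted), `binding_density` (spots/um^2)
#'   and `group_labels` (named character vector of design factors found in
#'   `Sample_Attributes`).
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  sect <- parse_rcc_sections(lines)
  if (is.null(sect$Code_Summary))
    stop("RCC format error in '", path, "': missing Code_Summary section")

  cs <- sect$Code_Summary
  if (length(cs) < 2L || !grepl("^CodeClass,", cs[[1L]]))
    stop("RCC format error in '", path,
         "': Code_Summary must start with a CodeClass,Name,Accession,Count header")
  body <- cs[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) != 4L)
  if (length(bad))
    stop("RCC format error in '", path, "': malformed Code_Summary row: ", body[bad[1L]])
  name <- vapply(fields, `[[`, "", 3L - 1L)
  cnt_chr <- vapply(fields, `[[`, "", 4L)
  ok <- grepl("^[0-9]+$", cnt_chr)
  if (!all(ok))
    stop("RCC format error in '", path, "': non-integer count '",
         cnt_chr[!ok][1L], "' for probe '", name[!ok][1L], "'")
  counts <- as.integer(cnt_chr)
  names(counts) <- name

  la <- rcc_kv(sect$Lane_Attributes)
  sa <- rcc_kv(sect$Sample_Attributes)
  if (is.na(la[["BindingDensity"]] %||% NA))
    stop("RCC format error in '", path, "': Lane_Attributes lacks BindingDensity")
  fov_count <- as.numeric(la[["FovCount"]] %||% NA)
  fov_counted <- as.numeric(la[["FovCounted"]] %||% NA)
  if (is.na(fov_count) || is.na(fov_counted))
    stop("RCC format error in '", path,
         "': Lane_Attributes lacks FovCount/FovCounted")

  reserved <- c("ID", "Owner", "Comments", "Date", "GeneRLF", "SystemAPF")
  groups <- sa[setdiff(names(sa), reserved)]

  sample_lane(sample_id = sa[["ID"]] %||% basename(path),
              counts = counts,
              fov_counted_pct = 100 * fov_counted / fov_count,
              binding_density = as.numeric(la[["BindingDensity"]]),
              group_labels = unlist(groups))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_rcc_sections <- function(lines) {
  starts <- grep("^<[A-Za-z_]+>$", lines)
  ends <- grep("^</[A-Za-z_]+>$", lines)
  out <- list()
  for (s in starts) {
    nm <- sub("^<([A-Za-z_]+)>$", "\\1", lines[s])
    e <- ends[ends > s]
    if (!length(e)) stop("RCC format error: unterminated section <", nm, ">")
    out[[nm]] <- lines[seq(s + 1L, e[1L] - 1L)]
  }
  out
}

rcc_kv <- function(lines) {
  if (is.null(lines)) return(list())
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexpr(",", lines), invert = TRUE)
  vals <- lapply(parts, function(p) if (length(p) == 2L) p[[2L]] else "")
  names(vals) <- vapply(parts, `[[`, "", 1L)
  vals
}

#' Construct a sample lane
#'
#' @param sample_id Lane/sample identifier.
#' @param counts Named non-negative integer vector of probe counts.
#' @param fov_counted_pct Percent of attempted imaging fields counted, in
#'   \[0, 100\].
#' @param binding_density Binding density in spots/um^2 (positive).
#' @param group_labels Named character vector mapping design factors to levels.
#' @return A `sample_lane` list.
#' @export
sample_lane <- function(sample_id, counts, fov_counted_pct, binding_density,
                        group_labels = character()) {
  stopifnot(length(sample_id) == 1L, !is.null(names(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("lane counts must be non-negative integers")
  if (fov_counted_pct < 0 || fov_counted_pct > 100)
    stop("fov_counted_pct must lie in [0, 100]")
  if (binding_density <= 0) stop("binding_density must be positive")
  structure(list(sample_id = as.character(sample_id),
                 counts = stats::setNames(as.integer(round(counts)), names(counts)),
                 fov_counted_pct = as.numeric(fov_counted_pct),
                 binding_density = as.numeric(binding_density),
                 group_labels = group_labels),
            class = "sample_lane")
}

#' Assemble lanes into a raw count matrix
#'
#' @param lanes List of `sample_lane` objects sharing one probe universe.
#' @return A `count_matrix` (scale `"raw"`), genes in rows in the order of the
#'   first lane, samples in columns in lane order.
#' @export
assemble_matrix <- function(lanes) {
  stopifnot(length(lanes) >= 1L)
  genes <- names(lanes[[1L]]$counts)
  for (ln in lanes) {
    if (!setequal(names(ln$counts), genes)) {
      d <- union(setdiff(names(ln$counts), genes), setdiff(genes, names(ln$counts)))
      stop("probe universe mismatch between lanes; differing probes: ",
           paste(d, collapse = ", "))
    }
  }
  vals <- vapply(lanes, function(ln) ln$counts[genes], numeric(length(genes)))
  vals <- matrix(vals, nrow = length(genes),
                 dimnames = list(genes, vapply(lanes, `[[`, "", "sample_id")))
  count_matrix(vals, scale = "raw")
}

#' Construct a count matrix
#'
#' A genes-by-samples numeric matrix tagged with its scale: `"raw"` (integer
#' counts), `"normalized"` (linear scale after lane normalization) or
#' `"log2"` (log2 of normalized counts).
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param scale One of `"raw"`, `"normalized"`, `"log2"`.
#' @return The matrix with class `count_matrix` and attribute `scale`.
#' @export
count_matrix <- function(values, scale = c("raw", "normalized", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (scale == "raw" && (any(values < 0) || any(values != round(values))))
    stop("raw count matrix must hold non-negative integers")
  if (scale == "log2" && any(!is.finite(values)))
    stop("log2 count matrix must be finite")
  structure(values, scale = scale, class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (scale: %s)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

cm_scale <- function(x) attr(x, "scale")

#' Write / read a count matrix as TSV (genes in rows)
#'
#' @param x A `count_matrix`.
#' @param path Output TSV path.
#' @rdname count_matrix_io
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(readLines(path), paste0("# scale: ", cm_scale(x))), path)
  invisible(path)
}

#' @param scale Scale tag to assume when the file carries no `# scale:` footer.
#' @rdname count_matrix_io
#' @export
read_count_matrix <- function(path, scale = "raw") {
  lines <- readLines(path)
  tag <- grep("^# scale: ", lines, value = TRUE)
  if (length(tag)) scale <- sub("^# scale: ", "", tag[[1L]])
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  count_matrix(m, scale = scale)
}

#' Read a probe annotation TSV
#'
#' Expected columns: `gene_id`, `code_class`, `concentration` (blank except
#' positives), `pathways` and `celltypes` (semicolon-separated lists).
#'
#' @param path Path to the tab-separated annotation file.
#' @return A `probe_annotation`; zero-row input yields an empty annotation.
#' @export
read_probe_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L) {
    return(probe_annotation(character(), character()))
  }
  split_semi <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                   function(v) v[nzchar(v)])
  probe_annotation(gene_id = df$gene_id,
                   code_class = df$code_class,
                   concentration = suppressWarnings(as.numeric(df$concentration)),
                   pathways = split_semi(df$pathways %||% rep("", nrow(df))),
                   celltypes = split_semi(df$celltypes %||% rep("", nrow(df))))
}

#' @rdname read_probe_annotations
#' @param ann A `probe_annotation`.
#' @export
write_probe_annotations <- function(ann, path) {
  df <- data.frame(gene_id = ann$gene_id,
                   code_class = ann$code_class,
                   concentration = ifelse(is.na(ann$concentration), "",
                                          format(ann$concentration, trim = TRUE)),
                   pathways = vapply(ann$pathways, paste, "", collapse = ";"),
                   celltypes = vapply(ann$celltypes, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param name Set name.
#' @param genes Non-empty character vector of unique gene identifiers
#'   (case-sensitive exact panel probe names).
#' @param theme Optional thematic grouping.
#' @param provenance Optional free-text origin of the list.
#' @return A `gene_set` list.
#' @export
gene_set <- function(name, genes, theme = "", provenance = "") {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) stop("gene set '", name, "' has duplicate genes")
  structure(list(name = name, genes = genes, theme = theme,
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%d genes%s)\n", x$name, length(x$genes),
              if (nzchar(x$theme)) paste0(", theme: ", x$theme) else ""))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file path (one set per line: name, description, genes).
#' @return `read_gmt`: a named list of `gene_set` objects.
#' @rdname gmt_io
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lines <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  desc <- stats::setNames(vapply(lines, `[[`, "", 2L),
                          vapply(lines, `[[`, "", 1L))
  out <- lapply(names(sets), function(nm)
    gene_set(nm, sets[[nm]], provenance = desc[[nm]]))
  stats::setNames(out, names(sets))
}

#' @param sets List of `gene_set` objects.
#' @rdname gmt_io
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$provenance)) s$provenance else s$theme,
            s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Build gene sets from the pathway annotations of a panel
#'
#' @param ann A `probe_annotation`.
#' @param min_genes Drop pathways annotated on fewer than this many probes.
#' @return Named list of `gene_set` objects (Endogenous probes only).
#' @export
pathway_gene_sets <- function(ann, min_genes = 1L) {
  endo <- ann[ann$code_class == "Endogenous", ]
  pws <- sort(unique(unlist(endo$pathways)))
  sets <- lapply(pws, function(pw) {
    g <- endo$gene_id[vapply(endo$pathways, function(p) pw %in% p, TRUE)]
    if (length(g) >= min_genes) gene_set(pw, g, provenance = "panel annotation")
  })
  names(sets) <- pws
  sets[!vapply(sets, is.null, TRUE)]
}

#' Marker gene sets per cell type from a panel annotation
#'
#' @param ann A `probe_annotation`.
#' @return Named list of `gene_set` objects, one per annotated cell type.
#' @export
celltype_gene_sets <- function(ann) {
  endo <- ann[ann$code_class == "Endogenous", ]
  cts <- sort(unique(unlist(endo$celltypes)))
  sets <- lapply(cts, function(ct) {
    g <- endo$gene_id[vapply(endo$celltypes, function(p) ct %in% p, TRUE)]
    gene_set(ct, g, theme = "cell type markers", provenance = "panel annotation")
  })
  stats::setNames(sets, cts)
}

#' Read / write the sample design table
#'
#' The design table assigns each sample its APP transgene level (`nTg` or
#' `APP`), its Arg1 level (`Arg1_suff` or `Arg1_insuff`), sex, and the number
#' of animals pooled into the lane.
#'
#' @param path TSV with columns `sample_id`, `APP`, `Arg1`, `sex`, `pool_size`.
#' @return A `design_table` data.frame with a derived `group` column
#'   (`<APP>.<Arg1>`).
#' @rdname design_io
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  design_table(df)
}

#' @param design A `design_table`.
#' @rdname design_io
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design)[, c("sample_id", "APP", "Arg1",
                                               "sex", "pool_size")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a design table
#'
#' @param df Data frame with columns `sample_id`, `APP` (levels `nTg`, `APP`),
#'   `Arg1` (levels `Arg1_suff`, `Arg1_insuff`) and optionally `sex`,
#'   `pool_size`.
#' @return A `design_table` with factor columns and a `group` label.
#' @export
design_table <- function(df) {
  stopifnot(all(c("sample_id", "APP", "Arg1") %in% names(df)))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in design table")
  if (!all(df$APP %in% c("nTg", "APP")))
    stop("APP column must use levels nTg / APP")
  if (!all(df$Arg1 %in% c("Arg1_suff", "Arg1_insuff")))
    stop("Arg1 column must use levels Arg1_suff / Arg1_insuff")
  df$APP <- factor(df$APP, levels = c("nTg", "APP"))
  df$Arg1 <- factor(df$Arg1, levels = c("Arg1_suff", "Arg1_insuff"))
  if (is.null(df$sex)) df$sex <- NA_character_
  if (is.null(df$pool_size)) df$pool_size <- NA_integer_
  df$group <- paste(df$APP, df$Arg1, sep = ".")
  class(df) <- c("design_table", "data.frame")
  df
}

#' Check that a design table covers a count matrix
#'
#' @param matrix A `count_matrix`.
#' @param design A `design_table`.
#' @return Invisibly `TRUE`; errors when a sample lacks a design row or a
#'   factorial cell is empty.
#' @export
validate_design <- function(matrix, design) {
  miss <- setdiff(colnames(matrix), design$sample_id)
  if (length(miss))
    stop("samples missing from design table: ", paste(miss, collapse = ", "))
  tab <- table(design$APP, design$Arg1)
  if (any(tab == 0L)) stop("factorial design has an empty cell")
  invisible(TRUE)
}
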