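PIGs	published 17-gene panel overlap	Apoe	Trem2	C4a	Cd9	Grn	Gusb	Npc2	C1qa	C1qb	C1qc	Csf1r	Cx3cr1	Hexb	Fcrls	Clu	Gfap	Man2b1
OLIGs	synthetic stand-in, published size 30	Mog	Mag	Mbp	Plp1	Mobp	Cnp	Mal	Opalin	Cldn11	Sox10	Olig1	Olig2	Gal3st1	Ugt8a	Fa2h	Pllp	Plxnb3	Aspa	Trf	Car2	Qdpr	Gjb1	Gjc2	Ermn	Sirt2	Tppp	Tppp3	Plekhb1	Gpr37	Cryab
DAM	synthetic stand-in, published size 15	Apoe	Trem2	Cd9	Gusb	Cst7	Lpl	Itgax	Clec7a	Axl	Ctsb	Ctsd	Ctsl	Tyrobp	Timp2	Cd63
HM	synthetic stand-in, published size 9	Cx3cr1	Hexb	Fcrls	Csf1r	P2ry12	Tmem119	Olfml3	Siglech	Sall1
MGnD	synthetic stand-in, published size 20	Apoe	C4a	Grn	Npc2	Axl	Clec7a	Itgax	Lgals3	Cybb	Spp1	Gpnmb	Fabp5	Lyz2	Msr1	Ccl2	Csf1	Cd74	B2m	Cd52	Lag3
M0	synthetic stand-in, published size 25	C1qa	C1qb	C1qc	Gpr34	Selplg	Mafb	Mef2a	Jun	Junb	Fos	Egr1	Klf2	Klf4	Tgfbr1	Tgfb1	Sparc	P2ry13	Entpd1	Adgrg1	Ltc4s	Fcgr1	Marcks	Rhob	Cd164	Serinc3
DAA	synthetic stand-in, published size 15	Clu	Gfap	Aqp4	Vim	Serpina3n	Cstb	Osmr	Gsn	Mt1	Mt2	Id3	Fxyd1	Ckb	Prdx6	Sparcl1
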