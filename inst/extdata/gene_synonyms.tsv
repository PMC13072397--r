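alias	canonical
cox1	cox1
coi	cox1
co1	cox1
coxi	cox1
cytochrome c oxidase subunit i	cox1
cytochrome c oxidase subunit 1	cox1
cox2	cox2
coii	cox2
co2	cox2
coxii	cox2
cytochrome c oxidase subunit ii	cox2
cytochrome c oxidase subunit 2	cox2
cox3	cox3
coiii	cox3
co3	cox3
coxiii	cox3
cytochrome c oxidase subunit iii	cox3
cytochrome c oxidase subunit 3	cox3
nad1	nad1
nd1	nad1
nadh1	nad1
nadh dehydrogenase subunit 1	nad1
nad2	nad2
nd2	nad2
nadh2	nad2
nadh dehydrogenase subunit 2	nad2
nad3	nad3
nd3	nad3
nadh3	nad3
nadh dehydrogenase subunit 3	nad3
nad4	nad4
nd4	nad4
nadh4	nad4
nadh dehydrogenase subunit 4	nad4
nad4l	nad4L
nd4l	nad4L
nadh4l	nad4L
nadh dehydrogenase subunit 4l	nad4L
nad5	nad5
nd5	nad5
nadh5	nad5
nadh dehydrogenase subunit 5	nad5
nad6	nad6
nd6	nad6
nadh6	nad6
nadh dehydrogenase subunit 6	nad6
atp6	atp6
atpase6	atp6
atp synthase f0 subunit 6	atp6
atp8	atp8
atpase8	atp8
atp synthase f0 subunit 8	atp8
cob	cob
cytb	cob
cyt b	cob
cytochrome b	cob
rrns	rrnS
12s	rrnS
12s rrna	rrnS
s-rrna	rrnS
small subunit ribosomal rna	rrnS
12s ribosomal rna	rrnS
rrnl	rrnL
16s	rrnL
16s rrna	rrnL
l-rrna	rrnL
large subunit ribosomal rna	rrnL
16s ribosomal rna	rrnL
cr	CR
d-loop	CR
control region	CR
at-rich region	CR
trna-ala	trnA
trna-arg	trnR
trna-asn	trnN
trna-asp	trnD
trna-cys	trnC
trna-gln	trnQ
trna-glu	trnE
trna-gly	trnG
trna-his	trnH
trna-ile	trnI
trna-lys	trnK
trna-met	trnM
trna-phe	trnF
trna-pro	trnP
trna-thr	trnT
trna-trp	trnW
trna-tyr	trnY
trna-val	trnV
trna-leu	trnL2
trna-leu(uur)	trnL2
trna-leu(taa)	trnL2
trna-leu(cun)	trnL1
trna-leu(tag)	trnL1
trna-leu1	trnL1
trna-leu2	trnL2
trna-ser	trnS2
trna-ser(ucn)	trnS2
trna-ser(tga)	trnS2
trna-ser(agn)	trnS1
trna-ser(gct)	trnS1
trna-ser1	trnS1
trna-ser2	trnS2
trna	trnA
trnr	trnR
trnn	trnN
trnd	trnD
trnc	trnC
trnq	trnQ
trne	trnE
trng	trnG
trnh	trnH
trni	trnI
trnk	trnK
trnm	trnM
trnf	trnF
trnp	trnP
trnt	trnT
trnw	trnW
trny	trnY
trnv	trnV
trnl1	trnL1
trnl2	trnL2
trns1	trnS1
trns2	trnS2
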