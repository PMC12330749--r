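term	namespace	identifier	name
AKT1	HGNC	AKT1	AKT1
HSF1	HGNC	HSF1	HSF1
TP53	HGNC	TP53	TP53
MDM2	HGNC	MDM2	MDM2
SIRT1	HGNC	SIRT1	SIRT1
PARP1	HGNC	PARP1	PARP1
ATM	HGNC	ATM	ATM
NAMPT	HGNC	NAMPT	NAMPT
EGFR	HGNC	EGFR	EGFR
EGF	HGNC	EGF	EGF
BRCA1	HGNC	BRCA1	BRCA1
CHEK2	HGNC	CHEK2	CHEK2
FOXO3	HGNC	FOXO3	FOXO3
kinase activity	GO	kinase activity	kinase activity
DNA repair	GO	DNA repair	DNA repair
apoptotic process	GO	apoptotic process	apoptotic process
NAD+	CHEBI	NAD(+)	NAD(+)
resveratrol	CHEBI	resveratrol	resveratrol
nicotinamide	CHEBI	nicotinamide	nicotinamide
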