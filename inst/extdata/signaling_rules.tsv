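node	class	expression	reference
Integrin	external	External signal	integrin binding to ECM
RTK	external	External signal	growth-factor receptor tyrosine kinase
E-cadherin	external	External signal	cell-cell adherens junctions
Wnt	external	External signal	Frizzled receptor engagement
APC	external	External signal	tumour suppressor, scenario flag
NF1	external	External signal	neurofibromin, negative regulator of Ras
beta-Catenin	internal	(Wnt Or Akt) And Not E-cadherin And Not APC	canonical Wnt effector, sequestered by junctional cadherin and APC
Grb-2/Sos	internal	RTK And Src	adaptor complex downstream of RTK
Src	internal	FAK	focal-adhesion kinase partner
FAK	internal	Integrin	focal adhesion kinase, integrin engaged
Rho-A	internal	FAK	small GTPase, adhesion driven
ROCK	internal	Rho-A	Rho-associated kinase
Rac-1	internal	PI3K And Not Rho-A	small GTPase, antagonized by Rho-A
Ras	internal	Grb-2/Sos And Not NF1	small GTPase, suppressed by neurofibromin
Raf-1	internal	Ras	MAPK cascade entry
MEK1/2	internal	Raf-1 Or Rac-1	MAPK kinase
ERK1/2	internal	MEK1/2	MAP kinase
RSK	internal	ERK1/2	p90 ribosomal S6 kinase
TSC	internal	Not RSK Or Not Akt	tuberous sclerosis complex, inhibited by RSK and Akt
mTORC	internal	Not TSC	mTOR complex, de-repressed by TSC loss
MNK	internal	ERK1/2	MAPK-interacting kinase
eIF4E	internal	MNK	translation initiation factor
MSK	internal	ERK1/2	mitogen- and stress-activated kinase
Fos	internal	MSK And RSK	AP-1 transcription factor
Myc	internal	ERK1/2 Or beta-Catenin	proliferation transcription factor
PI3K	internal	Ras	lipid kinase
Akt	internal	PI3K	survival kinase
eNOS	internal	Akt	endothelial nitric oxide synthase
NO	internal	eNOS	nitric oxide
Caspase	internal	Not NO	executioner caspases, inhibited by NO
Mdm2	internal	Akt	p53 ubiquitin ligase
p53	internal	Not Mdm2	tumour suppressor
Bax	internal	p53	pro-apoptotic effector (sink node)
Actin	internal	ROCK Or Rac-1	cytoskeletal remodelling
SNAIL	internal	beta-Catenin	EMT transcription factor
Cell growth	output	eIF4E Or mTORC	translation- and mTOR-driven mass increase
Cell proliferation	output	Fos And Myc	AP-1 and Myc driven cycling
Cell apoptosis	output	Caspase Or p53	caspase- or p53-mediated death
Cell migration	output	Actin And SNAIL	motility requires cytoskeleton and EMT program
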