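##gff-version 3
chrI	fixture	gene	121	200	.	+	.	ID=gA
chrI	fixture	CDS	121	200	.	+	0	ID=gA.cds;Parent=gA
chrI	fixture	gene	481	560	.	+	.	ID=gB
chrI	fixture	CDS	481	560	.	+	0	ID=gB.cds;Parent=gB
chrI	fixture	gene	721	730	.	+	.	ID=gC
chrI	fixture	CDS	721	730	.	+	0	ID=gC.cds;Parent=gC
chrI	fixture	gene	761	770	.	+	.	ID=gD
chrI	fixture	CDS	761	770	.	+	0	ID=gD.cds;Parent=gD
chrI	fixture	gene	1501	1600	.	+	.	ID=gE
chrI	fixture	CDS	1501	1600	.	+	0	ID=gE.cds;Parent=gE
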