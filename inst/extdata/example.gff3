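##gff-version 3
Chr1	example	gene	3631	5899	.	+	.	ID=AT1G01010
Chr1	example	mRNA	3631	5899	.	+	.	ID=AT1G01010.1;Parent=AT1G01010
Chr1	example	exon	3631	3913	.	+	.	Parent=AT1G01010.1
Chr1	example	exon	3996	4276	.	+	.	Parent=AT1G01010.1
Chr1	example	exon	4486	4605	.	+	.	Parent=AT1G01010.1
Chr1	example	gene	6788	9130	.	-	.	ID=AT1G01020
Chr1	example	mRNA	6788	9130	.	-	.	ID=AT1G01020.1;Parent=AT1G01020
Chr1	example	exon	6788	7069	.	-	.	Parent=AT1G01020.1
Chr1	example	exon	7157	7450	.	-	.	Parent=AT1G01020.1
Chr1	example	mRNA	6788	8737	.	-	.	ID=AT1G01020.2;Parent=AT1G01020
Chr1	example	exon	6788	7450	.	-	.	Parent=AT1G01020.2
ChrC	example	gene	54958	56397	.	-	.	ID=ATCG00490
ChrC	example	mRNA	54958	56397	.	-	.	ID=ATCG00490.1;Parent=ATCG00490
ChrC	example	exon	54958	56397	.	-	.	Parent=ATCG00490.1
ChrM	example	gene	11918	15171	.	+	.	ID=ATMG00020
ChrM	example	mRNA	11918	15171	.	+	.	ID=ATMG00020.1;Parent=ATMG00020
ChrM	example	exon	11918	15171	.	+	.	Parent=ATMG00020.1
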