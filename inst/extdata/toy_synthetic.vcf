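##fileformat=VCFv4.2
##contig=<ID=14,length=107043718>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
14	23886000	p.Arg1420Trp	G	A	100	PASS	DP=120
14	23884000	p.Arg1909Pro	C	G	100	PASS	DP=95
14	23890000	unrelated_record	T	C	100	PASS	DP=77
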