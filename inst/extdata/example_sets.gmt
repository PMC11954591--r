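GOBP_NEG_REG_TGFB_PRODUCTION	http://www.gsea-msigdb.org/gsea/msigdb/mouse/geneset/GOBP_NEGATIVE_REGULATION_OF_TRANSFORMING_GROWTH_FACTOR_BETA_PRODUCTION	Cd24a	Cd2ap	Cdh3	Fbln1	Fn1	Furin	Gata6	Il13	Laptm4b	Met	Tsku	Tyrobp
HALLMARK_TOY_DNA_REPAIR	na	Brca1	Brca2	Rad51	Xrcc4	Lig4
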