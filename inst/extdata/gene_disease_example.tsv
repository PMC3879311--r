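gene_id	disease_id
gene01	D_lymphoma
gene02	D_lymphoma
gene02	D_breast
gene03	D_breast
gene05	D_lymphoma
gene05	D_glioma
gene06	D_glioma
gene07	D_breast
gene08	D_lymphoma
gene09	D_glioma
gene10	D_breast
gene11	D_glioma
gene12	D_lymphoma
gene04	D_breast
gene02	D_glioma
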