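.datatable.aware <- TRUE

utils::globalVariables(c("region_id", "gene_id", "tf_pattern",
                         "gene_pattern", "sign", ".nsign"))
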