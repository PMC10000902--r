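modification	avg_delta	mono_delta	adds_groups
phospho	79.9799	79.96633	phospho1;phospho2
acetyl	42.0367	42.01057	NA
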