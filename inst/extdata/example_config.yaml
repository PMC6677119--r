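# Example analysis configuration: override any subset of the defaults.
disorder_threshold: 0.4
contact_cutoff: 8.0
ca_only: true
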