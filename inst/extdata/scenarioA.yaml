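name: scenarioA
quantity_metric: sample_size
include_crvs: false
criteria: [accuracy, relevance, consistency, timeliness, accessibility, improvement]
aggregation: unweighted
dea: {returns_to_scale: CRS, orientation: input, outputs_mode: qadi_single_output, pooling: consensus_only}
report_precision: 4
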