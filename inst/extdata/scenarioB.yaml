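name: scenarioB
quantity_metric: target_population
include_crvs: true
criteria: [accuracy, relevance, consistency, timeliness, accessibility]
aggregation: unweighted
dea: {returns_to_scale: CRS, orientation: input, outputs_mode: qadi_single_output, pooling: consensus_only}
report_precision: 4
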