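# Default detection basis: per-channel excursion intervals above the indoor
# baseline for each excretion event, plus the environment reference point.
channels:
  temperature:
    stool: [0.5, 2.0]
    urine: [1.8, .inf]
    both: [0.0, 1.0]
  humidity:
    stool: [5.0, 12.0]
    urine: [20.0, .inf]
    both: [12.0, 20.0]
  ammonia:
    stool: [1.0, 2.0]
    urine: [2.0, .inf]
    both: [1.0, 2.0]
environment:
  temperature: 22.0
  humidity: 40.0
  ammonia: 0.0
sensor_noise:
  temperature: 0.4
  humidity: 4.0
  ammonia: 0.6
reads_per_cycle: 2
bpa_alloc: consonant
mad_threshold: 3
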