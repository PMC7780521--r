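# The built-in Zambian 6-10-14 week DTP schedule, expressed in the
# structured format accepted by read_schedule(); edit a copy of this
# file to analyse a different national schedule (e.g. 2-4-6 months).
name: Zambia EPI 6-10-14 weeks (DTP)
min_first_age: 42
min_interval: 28
early_cutoff: 40
doses:
  - dose_number: 1
    target_age: 42
    window_start: 41
    window_end: 69
    label: DTP1
  - dose_number: 2
    target_age: 70
    window_start: 70
    window_end: 97
    label: DTP2
  - dose_number: 3
    target_age: 98
    window_start: 98
    window_end: 127
    label: DTP3
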