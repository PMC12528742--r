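dev_time_days,temp_C
109.79,15.0
141.13,15.0
66.25,15.0
87.12,17.5
62.08,17.5
70.29,17.5
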