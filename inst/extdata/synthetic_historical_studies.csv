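study_id,effect,se
SYN-01,-2.1,0.45
SYN-02,-1.6,0.60
SYN-03,-2.8,0.52
SYN-04,-1.9,0.38
SYN-05,-2.4,0.70
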