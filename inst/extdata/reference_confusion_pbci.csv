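true,low,mid,high
low,88.1,7.9,4.0
mid,9.8,80.3,9.9
high,3.7,10.4,85.9
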