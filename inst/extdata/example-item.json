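{"game":"assembly","rows":2,"cols":2,"cells":[1,9,12,1]}
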