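type	n
gain	144
loss	3372
mixed	22
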