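# fus_roi units=mm
-4	22
4	22
5	26
0	29
-5	26
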