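{"meta":{"package":"alginseq","version":"0.1.0"},"dp":4,"readouts":[{"cuts":0,"h4_dG":1,"h4_dM":3.2,"re_G":0,"re_M":1},{"cuts":1,"h4_dG":0,"h4_dM":1,"re_G":0,"re_M":1}]}
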