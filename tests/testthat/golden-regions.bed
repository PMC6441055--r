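chr15	5500	8500	fold=2.478	356	.
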