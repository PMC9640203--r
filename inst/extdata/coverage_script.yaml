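- option: Tell me more
- score: 5
- text: I am feeling a bit sad
- option: Practice gratitude
- text: my whanau and kai
- option: Get active
- option: "\U0001F60A"
- option: Finish up
- score: 4
- option: "\U0001F60A"

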