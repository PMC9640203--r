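self_harm:
  - kill myself
  - hurt myself
  - end my life
  - suicide
  - self harm
  - want to die
  - better off dead
  - end it all
abuse:
  - being abused
  - abuses me
  - hits me
  - hit me
  - not safe at home
  - hurts me at home

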