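# Cold-exposure scenario: winter ensemble in still 0 C air.
body: default
clothing: winter
fcl: 1.35
environment:
  Ta: 0
  RH: 0.85
options:
  met: 0.7
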