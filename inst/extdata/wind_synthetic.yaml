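seasons:
  DJF:
    shape: 2.2
    scale: 5.5
  MAM:
    shape: 2.0
    scale: 4.5
  JJA:
    shape: 2.1
    scale: 5.0
  SON:
    shape: 2.3
    scale: 6.5
direction_probs:
- 0.1914894
- 0.0851064
- 0.0212766
- 0.0212766
- 0.0212766
- 0.0212766
- 0.0212766
- 0.0212766
- 0.0212766
- 0.0212766
- 0.0212766
- 0.0212766
- 0.0212766
- 0.1276596
- 0.1914894
- 0.1702128
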