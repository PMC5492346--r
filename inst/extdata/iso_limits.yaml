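# Reference WBGT exposure limits (degrees C) by acclimatization status and
# ISO metabolic-rate class, for continuous work in light work clothing.
limits:
  acclimatized:
    rest: 33
    low: 30
    moderate: 28
    high: 25
    very_high: 23
  unacclimatized:
    rest: 32
    low: 29
    moderate: 26
    high: 22
    very_high: 18
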