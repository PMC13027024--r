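{
  "_comment": "SYNTHETIC example of the MSI decision-line file format (MSI iff a*mmr + b*hypermutator + c > 0). Placeholder values for testing only; the published classification parameters must be supplied by the user.",
  "a": 1,
  "b": 1,
  "c": 0
}
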