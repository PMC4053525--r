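# maps arbitrary source labels onto the canonical category levels
eeg:
  Normal: normal
  Abnormal: abnormal
  Not indicated: not_indicated
treatment:
  Immediate: immediate
  Deferred: delayed
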