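{
  "reads_in": 60,
  "adapter_found": 60,
  "discarded": 0,
  "classified": 60,
  "unassigned": 0,
  "ambiguous": 0,
  "aligned": 60,
  "majority_span_bases": 1,
  "majority_span_start": 85,
  "modal_length": 85
}
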