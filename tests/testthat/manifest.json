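{
  "subcommand": "frobnicate",
  "seed": 1,
  "package_version": "0.1.0",
  "timestamp": "2026-09-26 22:35:43",
  "parameters": [],
  "input_hashes": []
}
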