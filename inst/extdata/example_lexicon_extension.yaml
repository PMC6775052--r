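# Example lexicon extension: patterns listed here are appended to the
# built-in defaults (see ?load_lexicons for the schema).
ocs_keywords:
  - stem: ruminat
    match_mode: prefix
excl_risk_selfharm:
  - stem: reckless
    match_mode: prefix
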