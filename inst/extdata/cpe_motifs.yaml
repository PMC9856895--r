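# Default CPE motif set (non-authoritative; supply your study's list to
# reproduce published per-isoform counts).
canonical:
  - TTTTAT
  - TTTTAAT
  - TTTTTAT
noncanonical:
  - TTTTGT
  - TTTTGAT
  - TTTTTGT
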