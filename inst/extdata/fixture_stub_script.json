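{
  "1": [
    {
      "bel_statement": "act(p(HGNC:AKT1),ma(GO:\"kinase activity\")) directlyIncreases p(HGNC:HSF1,pmod(Ph,Ser,326))",
      "evidence": "The kinase activity of AKT1 phosphorylates HSF1 at serine 326."
    }
  ],
  "2": [
    {
      "bel_statement": "p(HGNC:TP53) increases p(HGNC:MDM2)",
      "evidence": "TP53 induces MDM2 expression."
    },
    {
      "bel_statement": "p(HGNC:MDM2) decreases p(HGNC:TP53)",
      "evidence": "MDM2 in turn decreases TP53 stability."
    }
  ],
  "3": [
    {
      "bel_statement": "p(HGNC:PARP1) decreases a(CHEBI:\"NAD(+)\")",
      "evidence": "PARP1 activation consumes NAD+."
    }
  ]
}
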