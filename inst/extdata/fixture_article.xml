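<?xml version="1.0" encoding="UTF-8"?>
<collection>
  <source>synthetic-fixture</source>
  <document>
    <id>PMC0000001</id>
    <passage>
      <infon key="section_type">TITLE</infon>
      <infon key="type">front</infon>
      <offset>0</offset>
      <text>Synthetic fixture article on AKT1 and NAD+ signaling</text>
    </passage>
    <passage>
      <infon key="section_type">ABSTRACT</infon>
      <infon key="type">abstract</infon>
      <offset>100</offset>
      <text>The kinase activity of AKT1 phosphorylates HSF1 at serine 326. Phosphorylated HSF1 is more active.</text>
      <annotation id="a1">
        <infon key="identifier">HGNC:AKT1</infon>
        <infon key="type">Gene</infon>
        <location offset="123" length="4"/>
        <text>AKT1</text>
      </annotation>
    </passage>
    <passage>
      <infon key="section_type">INTRO</infon>
      <infon key="type">paragraph</infon>
      <offset>300</offset>
      <text>TP53 induces MDM2 expression. MDM2 in turn decreases TP53 stability.</text>
      <annotation id="a2">
        <infon key="identifier">HGNC:TP53</infon>
        <infon key="type">Gene</infon>
        <location offset="300" length="4"/>
        <text>TP53</text>
      </annotation>
      <annotation id="a3">
        <infon key="identifier">HGNC:MDM2</infon>
        <infon key="type">Gene</infon>
        <location offset="313" length="4"/>
        <text>MDM2</text>
      </annotation>
    </passage>
    <passage>
      <infon key="section_type">RESULTS</infon>
      <infon key="type">paragraph</infon>
      <offset>500</offset>
      <text>PARP1 activation consumes NAD+. SIRT1 requires NAD+ for its deacetylase activity.</text>
    </passage>
    <passage>
      <infon key="section_type">RESULTS</infon>
      <infon key="type">paragraph</infon>
      <offset>700</offset>
      <text></text>
    </passage>
    <passage>
      <infon key="section_type">REF</infon>
      <infon key="type">ref</infon>
      <offset>800</offset>
      <text>1. Example A, Example B. A cited reference title. Journal of Examples. 2020.</text>
    </passage>
  </document>
</collection>
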