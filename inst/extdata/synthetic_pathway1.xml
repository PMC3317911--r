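<?xml version="1.0"?>
<!DOCTYPE pathway SYSTEM "https://www.kegg.jp/kegg/xml/KGML_v0.7.2_.dtd">
<!-- synthetic toy pathway: three chained reactions for testing -->
<pathway name="path:toy00001" org="toy" number="00001" title="Synthetic chain">
  <entry id="1" name="toy:E1" type="gene" reaction="rn:R0001"/>
  <entry id="2" name="toy:E2" type="gene" reaction="rn:R0002"/>
  <entry id="3" name="toy:E3a toy:E3b" type="gene" reaction="rn:R0003"/>
  <entry id="11" name="cpd:C0001" type="compound"/>
  <entry id="12" name="cpd:C0002" type="compound"/>
  <entry id="13" name="cpd:C0003" type="compound"/>
  <entry id="14" name="cpd:C0004" type="compound"/>
  <reaction id="21" name="rn:R0001" type="irreversible">
    <substrate id="11" name="cpd:C0001"/>
    <product id="12" name="cpd:C0002"/>
  </reaction>
  <reaction id="22" name="rn:R0002" type="reversible">
    <substrate id="12" name="cpd:C0002"/>
    <product id="13" name="cpd:C0003"/>
  </reaction>
  <reaction id="23" name="rn:R0003" type="irreversible">
    <substrate id="13" name="cpd:C0003"/>
    <product id="14" name="cpd:C0004"/>
  </reaction>
  <reaction id="24" name="rn:R0009" type="irreversible">
    <substrate id="11" name="cpd:C0001"/>
    <product id="14" name="cpd:C0004"/>
  </reaction>
</pathway>
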