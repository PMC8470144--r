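<?xml version="1.0"?>
<pathway name="path:syn00001" org="syn" number="00001" title="Synthetic three-step chain">
  <entry id="1" name="cpd:C90901" type="compound"/>
  <entry id="2" name="cpd:C90902" type="compound"/>
  <entry id="3" name="cpd:C90903" type="compound"/>
  <reaction id="10" name="rn:R90001" type="irreversible">
    <substrate id="1" name="cpd:C90901"/>
    <product id="2" name="cpd:C90902"/>
  </reaction>
  <reaction id="11" name="rn:R90002" type="reversible">
    <substrate id="2" name="cpd:C90902"/>
    <product id="3" name="cpd:C90903"/>
  </reaction>
</pathway>
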