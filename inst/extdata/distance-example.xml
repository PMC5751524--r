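<?xml version="1.0" encoding="UTF-8"?>
<document id="f2">
  <sentence id="f2.s0" text="The findings suggest that the dosage of S-ketamine should be reduced in patients receiving ticlopidine">
    <entity id="f2.s0.e1" charOffset="40-49" type="drug" text="S-ketamine"/>
    <entity id="f2.s0.e2" charOffset="91-101" type="drug" text="ticlopidine"/>
    <pair id="f2.s0.p1" e1="f2.s0.e1" e2="f2.s0.e2" ddi="true" type="mechanism"/>
  </sentence>
</document>
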