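<?xml version="1.0" encoding="UTF-8"?>
<document id="t1">
  <sentence id="t1.s0" text="The CNS-depressant effect of propoxyphene is additive with that of other CNS depressants, including alcohol">
    <entity id="t1.s0.e1" charOffset="29-40" type="drug" text="propoxyphene"/>
    <entity id="t1.s0.e2" charOffset="73-87" type="drug" text="CNS depressants"/>
    <entity id="t1.s0.e3" charOffset="100-106" type="drug" text="alcohol"/>
    <pair id="t1.s0.p1" e1="t1.s0.e1" e2="t1.s0.e2" ddi="false"/>
    <pair id="t1.s0.p2" e1="t1.s0.e1" e2="t1.s0.e3" ddi="false"/>
    <pair id="t1.s0.p3" e1="t1.s0.e2" e2="t1.s0.e3" ddi="false"/>
  </sentence>
</document>
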