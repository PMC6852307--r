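target,source
Czechoslovakia,Czech Republic
Czechoslovakia,Slovakia
Ethiopia PDR,Ethiopia
Ethiopia PDR,Eritrea
Sudan (former),Sudan
Sudan (former),South Sudan
USSR,Azerbaijan
USSR,Belarus
USSR,Estonia
USSR,Georgia
USSR,Kazakhstan
USSR,Kyrgyzstan
USSR,Latvia
USSR,Lithuania
USSR,Republic of Moldova
USSR,Russian Federation
USSR,Tajikistan
USSR,Turkmenistan
USSR,Ukraine
USSR,Uzbekistan
Yugoslav SFR,Bosnia and Herzegovina
Yugoslav SFR,Croatia
Yugoslav SFR,Montenegro
Yugoslav SFR,Serbia
Yugoslav SFR,Slovenia
Yugoslav SFR,The former Yugoslav Republic of Macedonia
Belgium-Luxembourg,Belgium
Belgium-Luxembourg,Luxembourg
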