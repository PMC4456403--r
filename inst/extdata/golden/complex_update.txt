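EGFR{CR!_, Y1148~p!1}-Shc{PTB!1, Y318~u} -> EGFR{CR!_, Y1148~p!1}-Shc{PTB!1, Y318~p} @ 1
EGFR{Y1148~p!1}-Shc{PTB!1, Y318~p!2}-Grb2{SH2!2, SH3!3}-SoS{a!3, b} + Ras{S1S2~gdp} -> EGFR{Y1148~p!1}-Shc{PTB!1, Y318~p!2}-Grb2{SH2!2, SH3!3}-SoS{a!3, b!4}-Ras{S1S2~gdp!4} @ 1
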