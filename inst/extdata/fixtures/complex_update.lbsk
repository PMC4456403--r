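// Complex abbreviation and update: the LHS complexes are named and the RHS
// is expressed as an update of the name.
agent EGFR = new {CR, Y1148};
agent Shc = new {PTB, Y318};
agent Grb2 = new {SH2, SH3};
agent SoS = new {a, b};
agent Ras = new {S1S2:(gdp gtp)};

agent c1 = EGFR{CR!_, Y1148~p!1}-Shc{PTB!1, Y318~u};
c1 -> c1<Shc{Y318~p}>|

agent c2 = EGFR{Y1148~p!1}-Shc{PTB!1, Y318~p!2}-Grb2{SH2!2, SH3!3}-SoS{a!3, b};
c2 + Ras{S1S2~gdp} -> c2<SoS{b!4}>-Ras{S1S2~gdp!4}
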