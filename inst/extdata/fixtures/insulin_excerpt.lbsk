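// Insulin signalling excerpt: PDK1 phosphorylates PKCz through the standard
// bind/phosphorylate/unbind triple (bpu3), and Akt binds, phosphorylates
// and releases AS160.  The bpu3, pho and unbind module skeletons and agent
// signatures are minimal synthetic reconstructions: the full model is not
// transcribed here.
module bpu3(agent k:{a, b}, s:{c, d}){
  k{b} + s{c~u, d} -> k{b!1}-s{c~u, d!1}|
  k{b!1}-s{c~u, d!1} -> k{b!1}-s{c~p, d!1}|
  k{b!1}-s{d!1} -> k{b} + s{d}
};
module pho(agent c:s{m}){
  c -> c<s{m~p!e}>
};
module unbind(agent a:{m}, b:{n}){
  a{m!1}-b{n!1} -> a{m} + b{n}
};

agent PDK1 = new {PH, pkc};
agent PKCz = new {T410, pdk1};
agent Akt = new {as160, S473, T308};
agent AS160 = new {gap};
agent Rab10 = new {g};

bpu3(PDK1{PH}:{PH, pkc}, PKCz:{T410, pdk1})|

Akt{as160, S473~p, T308~p} + AS160{gap~u!1}-Rab10{g~u!1} ->
  Akt{as160!1, S473~p, T308~u}-AS160{gap~u!1} + Rab10{g~u}|

pho(Akt{as160!1}-AS160{gap~u!1}: AS160{gap})|
unbind(Akt:{as160}, AS160:{gap})
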