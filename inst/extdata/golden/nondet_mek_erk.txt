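MEK1{D} + ERK1{CD} -> MEK1{D!1}-ERK1{CD!1} @ 1
MEK1{D} + ERK2{CD} -> MEK1{D!1}-ERK2{CD!1} @ 1
MEK2{D} + ERK1{CD} -> MEK2{D!1}-ERK1{CD!1} @ 1
MEK2{D} + ERK2{CD} -> MEK2{D!1}-ERK2{CD!1} @ 1
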