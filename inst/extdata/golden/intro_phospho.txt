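Raf{x} + MEK{S222~u} -> Raf{x!1}-MEK{S222~u!1} @ 1
Raf{x!1}-MEK{S222~u!1} -> Raf{x!1}-MEK{S222~p!1} @ 1
Raf{x!1}-MEK{S222!1} -> Raf{x} + MEK{S222} @ 1
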