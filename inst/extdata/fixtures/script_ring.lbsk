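// Initial condition of the chemotactic switch: a closed ring of 34
// protomers, each bound x-to-y to its neighbour (indices modulo 34).
//
// Transliterated from the F# original:
//   "init " + (seq{ for i in 1.. 34 ->
//     "P(f~0, s, x!" + string(i%34) + ", y!" + string((i+1)%34) + ")" }
//     |> String.concat "-") + " 1;"
// The original leaves internal states of s, x and y unspecified; ground
// values (s~u, x~0, y~0) are emitted here so the initial condition contains
// no wild cards.
agent P = new {f:(0 1), x:(0 1), y:(0 1), s};

script {
  i <- seq_len(34)
  paste0("init ",
         paste(sprintf("P{f~0, s~u, x~0!%d, y~0!%d}", i %% 34, (i + 1) %% 34),
               collapse = "-"),
         " 1;")
};
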