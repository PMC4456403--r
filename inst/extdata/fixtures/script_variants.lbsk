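// A hundred variants of an agent generated by an embedded script and
// combined into one non-deterministic agent S; the degradation rule after
// the script expands to one rule per variant.
//
// Transliterated from the F# original:
//   let generate name num =
//     let agentNames = seq {for i in 1.. num -> name + string(i)} in
//     let newDefsLst = Seq.map (fun s -> "agent " + s + " = new{};") agentNames in
//     let newDefsStr = String.concat "\n" newDefsLst in
//     let choiceStr = "agent " + name + " = " + (String.concat " or " agentNames) in
//     newDefsStr + "\n" + choiceStr
scriptdef {
  generate <- function(name, num) {
    agentNames <- paste0(name, seq_len(num))
    newDefs <- paste0("agent ", agentNames, " = new{};", collapse = "\n")
    choice <- paste0("agent ", name, " = ",
                     paste(agentNames, collapse = " or "), ";")
    paste0(newDefs, "\n", choice)
  }
};

script {
  generate("S", 100)
};

S ->
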