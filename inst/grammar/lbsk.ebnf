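(* Concrete grammar of the .lbsk dialect accepted by lbskappa.
   ASCII operator spellings are shown; the typeset forms
   "→" (->), "↔" (<->), "⟨⟩"/"〈〉" (< >), "˜" (~) and "−" (-) are
   normalised to them before tokenisation.  "//" starts a line comment. *)

program        = { statement , separator } , [ statement ] ;
separator      = ";" | "|" ;

statement      = definition
               | located
               | rule
               | invocation
               | init
               | script-block
               | scriptdef-block
               | "nil" ;

definition     = agent-def | comp-def | rate-def | module-def ;
agent-def      = "agent" , ident , { "," , ident } , "=" , agent-expr ;
                 (* an identifier list (aliases) only with a new-expression *)
comp-def       = "comp" , ident , [ "inside" , ident ] ;
rate-def       = "rate" , ident , "=" , rate-expr ;
module-def     = "module" , ident , "(" , [ formals ] , ")" ,
                 "{" , program , "}" ;

formals        = formal-group , { ( ";" | "," ) , formal-group } ;
formal-group   = [ "agent" | "rate" | "comp" ] , formal-entry ;
                 (* the keyword persists for following entries *)
formal-entry   = ident , [ ":" ] , [ annotation ]   (* agent formals *)
               | ident ;                            (* rate and comp formals *)

located        = ident , "[" , program , "]" ;
init           = "init" , agent-expr , integer ;
invocation     = ident , "(" , [ actual , { "," , actual } ] , ")" ;
actual         = rate-expr
               | agent-expr , [ ":" , annotation ]
               | ident ;

rule           = [ term-list ] , arrow , [ rates ] , [ term-list ] ;
arrow          = "->" | "<->" ;
rates          = "{" , rate-expr , "}" , [ "{" , rate-expr , "}" ] ;
                 (* the second group is the reverse rate of "<->" *)
term-list      = term , { "+" , term } ;
term           = agent-expr , [ "as" , ident ] ;

agent-expr     = choice ;
choice         = composition , { "or" , composition } ;
composition    = postfix , { "-" , postfix } ;
postfix        = primary , { update } ;
update         = "<" , ident , [ site-block ] , ">" ;
primary        = "new" , [ ident ] , signature
               | ident , site-block          (* literal: sugar for an update *)
               | ident , "[" , agent-expr , "]"
               | ident ;

signature      = "{" , [ sig-entry , { "," , sig-entry } ] , "}" ;
sig-entry      = ident , [ ":" , "(" , value , { value } , ")" ] ;
                 (* omitted value sets default to (u p) *)

site-block     = "{" , [ site-expr , { "," , site-expr } ] , "}" ;
site-expr      = ident , [ internal ] , [ link ] ;
internal       = "~" , ( value | "?" ) ;
link           = "!" , ( integer | "_" | "?" | "e" ) | "?" ;
                 (* "!_" bound to something, "!?" or bare "?" free or bound,
                    "!e" identity (only meaningful inside updates);
                    an omitted link is free inside an update site block *)

rate-expr      = rate-atom , { ( "*" | "/" ) , rate-atom } ;
rate-atom      = number | ident ;

script-block    = "script" , "{" , host-code , "}" ;
scriptdef-block = "scriptdef" , "{" , host-code , "}" ;
                 (* host-code is R source captured verbatim up to the
                    balancing brace; scriptdef bodies may only contain
                    top-level assignments *)

value          = ident | integer ;
ident          = letter , { letter | digit | "_" | "'" } ;
integer        = digit , { digit } ;
number         = integer , [ "." , integer ] , [ exponent ] ;
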