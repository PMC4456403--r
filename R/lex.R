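# Lexer for the concrete LBS-kappa dialect.
#
# Both the typeset glyphs used in print (arrows, angle brackets, small tilde,
# minus sign) and plain-ASCII spellings are accepted; the pretty-printer and
# all fixtures emit ASCII.

lbsk_keywords <- c("module", "agent", "rate", "comp", "new", "init", "or",
                   "as", "inside", "script", "scriptdef", "nil")

# Unicode forms normalised before tokenisation.  U+2192 arrow, U+2194 double
# arrow, U+27E8/27E9 and U+3008/3009 angle brackets, U+02DC small tilde,
# U+2212 minus.
normalise_source <- function(src) {
  subs <- c(
    "→" = "->", "↔" = "<->",
    "⟨" = "<", "⟩" = ">",
    "〈" = "<", "〉" = ">",
    "˜" = "~", "−" = "-"
  )
  for (from in names(subs)) {
    src <- gsub(from, subs[[from]], src, fixed = TRUE)
  }
  src
}

lbsk_parse_error <- function(msg, line = NA_integer_, col = NA_integer_) {
  loc <- if (!is.na(line)) sprintf(" at line %d, column %d", line, col) else ""
  stop(errorCondition(paste0("parse error", loc, ": ", msg),
                      class = c("lbsk_parse_error", "lbsk_error")))
}

token <- function(type, value, line, col) {
  list(type = type, value = value, line = line, col = col)
}

# Tokenise a full program.  Script block bodies are captured raw (balanced
# braces, quote-aware) because they contain host-language code, not LBS-kappa.
tokenize <- function(src) {
  src <- normalise_source(src)
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- vector("list", 256)
  ntok <- 0L
  push <- function(tk) {
    ntok <<- ntok + 1L
    if (ntok > length(toks)) toks[[2L * ntok]] <<- NULL
    toks[[ntok]] <<- tk
  }
  i <- 1L
  line <- 1L
  col <- 1L
  adv <- function(k = 1L) {
    for (j in seq_len(k)) {
      if (i <= n && chars[[i]] == "\n") {
        line <<- line + 1L
        col <<- 1L
      } else {
        col <<- col + 1L
      }
      i <<- i + 1L
    }
  }
  peek <- function(k = 0L) if (i + k <= n) chars[[i + k]] else ""

  is_ident_start <- function(ch) grepl("[A-Za-z]", ch)
  is_ident_char <- function(ch) grepl("[A-Za-z0-9_']", ch)
  is_digit <- function(ch) grepl("[0-9]", ch)

  scan_script_body <- function() {
    # Called with i at the opening '{'.  Returns raw text between the braces.
    depth <- 0L
    start_line <- line
    start_col <- col
    adv() # consume '{'
    buf_start <- i
    depth <- 1L
    in_str <- ""
    while (i <= n) {
      ch <- chars[[i]]
      if (nzchar(in_str)) {
        if (ch == "\\") {
          adv(2L)
          next
        }
        if (ch == in_str) in_str <- ""
        adv()
        next
      }
      if (ch == "\"" || ch == "'") {
        in_str <- ch
        adv()
        next
      }
      if (ch == "{") depth <- depth + 1L
      if (ch == "}") {
        depth <- depth - 1L
        if (depth == 0L) {
          body <- paste(chars[buf_start:(i - 1L)], collapse = "")
          adv() # consume '}'
          return(body)
        }
      }
      adv()
    }
    lbsk_parse_error("unterminated script block", start_line, start_col)
  }

  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% c(" ", "\t", "\r", "\n")) {
      adv()
      next
    }
    if (ch == "/" && peek(1L) == "/") {
      while (i <= n && chars[[i]] != "\n") adv()
      next
    }
    tl <- line
    tc <- col
    if (is_ident_start(ch)) {
      j <- i
      while (j <= n && is_ident_char(chars[[j]])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      adv(j - i)
      if (word %in% c("script", "scriptdef")) {
        # skip whitespace/comments up to '{'
        repeat {
          if (i <= n && chars[[i]] %in% c(" ", "\t", "\r", "\n")) {
            adv()
          } else if (i < n && chars[[i]] == "/" && chars[[i + 1L]] == "/") {
            while (i <= n && chars[[i]] != "\n") adv()
          } else break
        }
        if (i > n || chars[[i]] != "{") {
          lbsk_parse_error(sprintf("expected '{' after '%s'", word), line, col)
        }
        body <- scan_script_body()
        push(token(paste0("kw_", word), body, tl, tc))
      } else if (word %in% lbsk_keywords) {
        push(token(paste0("kw_", word), word, tl, tc))
      } else {
        push(token("ident", word, tl, tc))
      }
      next
    }
    if (is_digit(ch)) {
      j <- i
      while (j <= n && is_digit(chars[[j]])) j <- j + 1L
      if (j <= n && chars[[j]] == "." && j < n && is_digit(chars[[j + 1L]])) {
        j <- j + 1L
        while (j <= n && is_digit(chars[[j]])) j <- j + 1L
      }
      if (j <= n && chars[[j]] %in% c("e", "E") &&
          ((j < n && is_digit(chars[[j + 1L]])) ||
           (j + 1L < n && chars[[j + 1L]] %in% c("+", "-") &&
            is_digit(chars[[j + 2L]])))) {
        j <- j + 1L
        if (chars[[j]] %in% c("+", "-")) j <- j + 1L
        while (j <= n && is_digit(chars[[j]])) j <- j + 1L
      }
      num <- paste(chars[i:(j - 1L)], collapse = "")
      adv(j - i)
      push(token("number", num, tl, tc))
      next
    }
    three <- paste0(ch, peek(1L), peek(2L))
    two <- paste0(ch, peek(1L))
    if (three == "<->") {
      push(token("revarrow", "<->", tl, tc))
      adv(3L)
      next
    }
    if (two == "->") {
      push(token("arrow", "->", tl, tc))
      adv(2L)
      next
    }
    simple <- c("{" = "lbrace", "}" = "rbrace", "(" = "lparen", ")" = "rparen",
                "[" = "lbracket", "]" = "rbracket", "<" = "langle",
                ">" = "rangle", "|" = "pipe", ";" = "semi", "," = "comma",
                "+" = "plus", "-" = "dash", "=" = "equals", ":" = "colon",
                "~" = "tilde", "!" = "bang", "*" = "star", "/" = "slash",
                "?" = "question", "_" = "underscore", "." = "dot")
    if (!is.na(simple[ch])) {
      push(token(unname(simple[ch]), ch, tl, tc))
      adv()
      next
    }
    lbsk_parse_error(sprintf("unexpected character '%s'", ch), tl, tc)
  }
  push(token("eof", "", line, col))
  toks[seq_len(ntok)]
}
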