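# Recursive-descent parser producing the abstract syntax.

new_stream <- function(toks) {
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st
}

cur <- function(st) st$toks[[st$pos]]
cur_type <- function(st) st$toks[[st$pos]]$type
peek_type <- function(st, k = 1L) {
  p <- st$pos + k
  if (p <= length(st$toks)) st$toks[[p]]$type else "eof"
}
advance <- function(st) {
  tk <- st$toks[[st$pos]]
  if (st$pos < length(st$toks)) st$pos <- st$pos + 1L
  tk
}
expect <- function(st, type, what = type) {
  tk <- cur(st)
  if (tk$type != type) {
    lbsk_parse_error(sprintf("expected %s but found '%s'", what,
                             if (nzchar(tk$value)) tk$value else tk$type),
                     tk$line, tk$col)
  }
  advance(st)
}

#' Parse an LBS-kappa program
#'
#' Turns concrete source text into an abstract syntax tree.  The dialect
#' accepts both ASCII (`->`, `<->`, `< >`, `~`) and the typeset glyph forms
#' of the operators; `//` starts a line comment.  An empty input parses to
#' the nil program.
#'
#' @param text Program source, a character vector (joined with newlines).
#' @return An abstract syntax tree (`lbsk_node`); pass to [lbsk_desugar()] or
#'   [lbsk_compile()].
#' @examples
#' ast <- lbsk_parse("agent A = new {x}; A{x~u} -> {0.1} A{x~p}")
#' @export
lbsk_parse <- function(text) {
  src <- paste(text, collapse = "\n")
  st <- new_stream(tokenize(src))
  prog <- parse_block(st, "eof")
  expect(st, "eof", "end of input")
  prog
}

stmt_separators <- c("semi", "pipe")

parse_block <- function(st, stopper) {
  stmts <- list()
  repeat {
    if (cur_type(st) %in% c(stopper, "eof")) break
    while (cur_type(st) %in% stmt_separators) advance(st)
    if (cur_type(st) %in% c(stopper, "eof")) break
    stmts[[length(stmts) + 1L]] <- parse_statement(st)
    if (cur_type(st) %in% stmt_separators) {
      advance(st)
    } else if (!cur_type(st) %in% c(stopper, "eof")) {
      tk <- cur(st)
      lbsk_parse_error(sprintf("expected ';', '|' or end of block before '%s'",
                               if (nzchar(tk$value)) tk$value else tk$type),
                       tk$line, tk$col)
    }
  }
  nest_statements(stmts)
}

# Right-nest a statement list: definitions scope over the remainder of the
# block, everything else is parallel composition.
nest_statements <- function(stmts) {
  acc <- ast_nil()
  for (stmt in rev(stmts)) {
    if (inherits(stmt, "lbsk_node") &&
        stmt$kind %in% c("agent_def", "comp_def", "rate_def", "module_def")) {
      acc <- ast_scoped(stmt, acc)
    } else if (is.list(stmt) && identical(stmt$kind, "script_stmt")) {
      acc <- ast_script(stmt$code, acc)
    } else if (is.list(stmt) && identical(stmt$kind, "scriptdef_stmt")) {
      acc <- ast_scriptdef(stmt$code, acc)
    } else if (identical(acc$kind, "nil")) {
      acc <- stmt
    } else {
      acc <- ast_parallel(stmt, acc)
    }
  }
  acc
}

parse_statement <- function(st) {
  type <- cur_type(st)
  if (type == "kw_module") return(parse_module_def(st))
  if (type == "kw_agent") return(parse_agent_def(st))
  if (type == "kw_comp") return(parse_comp_def(st))
  if (type == "kw_rate") return(parse_rate_def(st))
  if (type == "kw_init") return(parse_init(st))
  if (type == "kw_nil") {
    advance(st)
    return(ast_nil())
  }
  if (type == "kw_script") {
    tk <- advance(st)
    return(list(kind = "script_stmt", code = tk$value))
  }
  if (type == "kw_scriptdef") {
    tk <- advance(st)
    return(list(kind = "scriptdef_stmt", code = tk$value))
  }
  if (type == "ident" && peek_type(st) == "lparen") {
    return(parse_invocation(st))
  }
  if (type == "ident" && peek_type(st) == "lbracket" &&
      !bracket_starts_rule(st)) {
    id <- advance(st)$value
    expect(st, "lbracket", "'['")
    body <- parse_block(st, "rbracket")
    expect(st, "rbracket", "']'")
    return(ast_located(id, body))
  }
  parse_rule(st)
}

# Lookahead to distinguish a located program `cell[ ... ]` from a rule whose
# first agent is located, `nucleus[mRNA] -> mRNA`.
bracket_starts_rule <- function(st) {
  depth <- 0L
  p <- st$pos + 1L # at the lbracket
  n <- length(st$toks)
  while (p <= n) {
    ty <- st$toks[[p]]$type
    if (ty == "lbracket") depth <- depth + 1L
    if (ty == "rbracket") {
      depth <- depth - 1L
      if (depth == 0L) {
        after <- if (p < n) st$toks[[p + 1L]]$type else "eof"
        return(after %in% c("arrow", "revarrow", "plus", "dash", "kw_or",
                            "kw_as", "langle"))
      }
    }
    if (ty == "eof") break
    p <- p + 1L
  }
  tk <- cur(st)
  lbsk_parse_error("unbalanced '['", tk$line, tk$col)
}

# --- definitions -------------------------------------------------------------

parse_agent_def <- function(st) {
  expect(st, "kw_agent", "'agent'")
  ids <- expect(st, "ident", "agent identifier")$value
  while (cur_type(st) == "comma") {
    advance(st)
    ids <- c(ids, expect(st, "ident", "agent identifier")$value)
  }
  expect(st, "equals", "'='")
  expr <- parse_agent_or(st)
  ast_agent_def(ids, expr)
}

parse_comp_def <- function(st) {
  expect(st, "kw_comp", "'comp'")
  id <- expect(st, "ident", "compartment identifier")$value
  parent <- NULL
  if (cur_type(st) == "kw_inside") {
    advance(st)
    parent <- expect(st, "ident", "parent compartment")$value
  }
  ast_comp_def(id, parent)
}

parse_rate_def <- function(st) {
  expect(st, "kw_rate", "'rate'")
  id <- expect(st, "ident", "rate identifier")$value
  expect(st, "equals", "'='")
  ast_rate_def(id, parse_rate_expr(st))
}

parse_module_def <- function(st) {
  expect(st, "kw_module", "'module'")
  id <- expect(st, "ident", "module identifier")$value
  expect(st, "lparen", "'('")
  formals <- list(comps = character(), agents = list(), rates = character())
  kind <- NULL
  while (cur_type(st) != "rparen") {
    if (cur_type(st) == "kw_agent") {
      kind <- "agent"
      advance(st)
    } else if (cur_type(st) == "kw_rate") {
      kind <- "rate"
      advance(st)
    } else if (cur_type(st) == "kw_comp") {
      kind <- "comp"
      advance(st)
    }
    if (is.null(kind)) {
      tk <- cur(st)
      lbsk_parse_error("module formals must start with 'agent', 'rate' or 'comp'",
                       tk$line, tk$col)
    }
    fid <- expect(st, "ident", "formal parameter name")$value
    if (kind == "agent") {
      ann <- NULL
      if (cur_type(st) == "colon") {
        advance(st)
        ann <- parse_annotation(st)
      } else if (cur_type(st) == "lbrace") {
        # `agent a{m}` abbreviates `agent a : {m}`
        ann <- parse_annotation(st)
      }
      formals$agents[[length(formals$agents) + 1L]] <- list(id = fid, ann = ann)
    } else if (kind == "rate") {
      formals$rates <- c(formals$rates, fid)
    } else {
      formals$comps <- c(formals$comps, fid)
    }
    if (cur_type(st) %in% c("comma", "semi")) advance(st)
  }
  expect(st, "rparen", "')'")
  expect(st, "lbrace", "'{'")
  body <- parse_block(st, "rbrace")
  expect(st, "rbrace", "'}'")
  ast_module_def(id, formals, body)
}

parse_init <- function(st) {
  expect(st, "kw_init", "'init'")
  expr <- parse_agent_or(st)
  tk <- expect(st, "number", "initial copy number")
  count <- as.numeric(tk$value)
  if (count != floor(count) || count <= 0) {
    lbsk_parse_error("initial copy number must be a positive integer",
                     tk$line, tk$col)
  }
  ast_init(expr, as.integer(count))
}

# --- rules -------------------------------------------------------------------

parse_rule <- function(st) {
  lhs <- parse_agent_term_list(st)
  reversible <- FALSE
  if (cur_type(st) == "revarrow") {
    reversible <- TRUE
    advance(st)
  } else {
    expect(st, "arrow", "'->' or '<->'")
  }
  fwd <- NULL
  rev <- NULL
  if (cur_type(st) == "lbrace") {
    advance(st)
    fwd <- parse_rate_expr(st)
    expect(st, "rbrace", "'}' closing the rate")
  }
  if (reversible && cur_type(st) == "lbrace") {
    advance(st)
    rev <- parse_rate_expr(st)
    expect(st, "rbrace", "'}' closing the reverse rate")
  }
  rhs <- if (cur_type(st) %in% c("ident", "kw_new")) {
    parse_agent_term_list(st)
  } else {
    list()
  }
  if (length(lhs) == 0L && length(rhs) == 0L) {
    tk <- cur(st)
    lbsk_parse_error("a rule needs agents on at least one side", tk$line, tk$col)
  }
  ast_rule(lhs, rhs, fwd = fwd, rev = rev, reversible = reversible)
}

parse_agent_term_list <- function(st) {
  if (!cur_type(st) %in% c("ident", "kw_new")) return(list())
  terms <- list(parse_agent_term(st))
  while (cur_type(st) == "plus") {
    advance(st)
    terms[[length(terms) + 1L]] <- parse_agent_term(st)
  }
  terms
}

parse_agent_term <- function(st) {
  expr <- parse_agent_or(st)
  as_id <- NULL
  if (cur_type(st) == "kw_as") {
    advance(st)
    as_id <- expect(st, "ident", "identifier after 'as'")$value
  }
  list(expr = expr, as = as_id)
}

# --- agent expressions -------------------------------------------------------

parse_agent_or <- function(st) {
  left <- parse_agent_compose(st)
  while (cur_type(st) == "kw_or") {
    advance(st)
    left <- ast_choice(left, parse_agent_compose(st))
  }
  left
}

parse_agent_compose <- function(st) {
  left <- parse_agent_postfix(st)
  while (cur_type(st) == "dash") {
    advance(st)
    left <- ast_compose(left, parse_agent_postfix(st))
  }
  left
}

parse_agent_postfix <- function(st) {
  e <- parse_agent_primary(st)
  while (cur_type(st) == "langle") {
    advance(st)
    target <- expect(st, "ident", "update target agent name")$value
    sites <- list()
    if (cur_type(st) == "lbrace") sites <- parse_site_block(st)
    expect(st, "rangle", "'>' closing the update")
    e <- ast_update(e, target, sites)
  }
  e
}

parse_agent_primary <- function(st) {
  type <- cur_type(st)
  if (type == "kw_new") {
    advance(st)
    name <- NULL
    if (cur_type(st) == "ident") name <- advance(st)$value
    sig <- parse_signature(st)
    return(ast_new_agent(name, sig))
  }
  if (type == "ident") {
    id <- advance(st)$value
    if (cur_type(st) == "lbrace") {
      return(ast_literal(id, parse_site_block(st)))
    }
    if (cur_type(st) == "lbracket") {
      advance(st)
      body <- parse_agent_or(st)
      expect(st, "rbracket", "']'")
      return(ast_loc_expr(id, body))
    }
    return(ast_ident(id))
  }
  tk <- cur(st)
  lbsk_parse_error(sprintf("expected an agent expression, found '%s'",
                           if (nzchar(tk$value)) tk$value else tk$type),
                   tk$line, tk$col)
}

# Site assignment block {n~v!1, m!_, ...} used in literals and updates.
parse_site_block <- function(st) {
  open <- expect(st, "lbrace", "'{'")
  entries <- list()
  seen <- character()
  while (cur_type(st) != "rbrace") {
    nm_tok <- expect(st, "ident", "site name")
    nm <- nm_tok$value
    if (nm %in% seen) {
      lbsk_parse_error(sprintf("duplicate site '%s' in one agent literal", nm),
                       nm_tok$line, nm_tok$col)
    }
    seen <- c(seen, nm)
    internal <- NULL
    link <- NULL
    if (cur_type(st) == "tilde") {
      advance(st)
      if (cur_type(st) == "question") {
        advance(st)
        internal <- int_wildcard()
      } else if (cur_type(st) %in% c("ident", "number")) {
        internal <- int_value(advance(st)$value)
      } else {
        tk <- cur(st)
        lbsk_parse_error("expected an internal state value after '~'",
                         tk$line, tk$col)
      }
    }
    if (cur_type(st) == "question") {
      advance(st)
      link <- link_any()
    } else if (cur_type(st) == "bang") {
      advance(st)
      ty <- cur_type(st)
      if (ty == "number") {
        k <- as.numeric(advance(st)$value)
        link <- link_label(as.integer(k))
      } else if (ty == "underscore") {
        advance(st)
        link <- link_bound()
      } else if (ty == "question") {
        advance(st)
        link <- link_any()
      } else if (ty == "ident" && cur(st)$value == "e") {
        advance(st)
        link <- link_identity()
      } else {
        tk <- cur(st)
        lbsk_parse_error("expected a link label, '_', '?' or 'e' after '!'",
                         tk$line, tk$col)
      }
    }
    entries[[length(entries) + 1L]] <- site_entry(nm, internal, link)
    if (cur_type(st) == "comma") advance(st) else break
  }
  if (cur_type(st) != "rbrace") {
    lbsk_parse_error("unbalanced '{' in site block", open$line, open$col)
  }
  advance(st)
  entries
}

# Signature block of a `new` agent: {site:(v1 v2), site, ...}
parse_signature <- function(st) {
  open <- expect(st, "lbrace", "'{'")
  sig <- list()
  while (cur_type(st) != "rbrace") {
    nm_tok <- expect(st, "ident", "site name")
    nm <- nm_tok$value
    if (nm %in% names(sig)) {
      lbsk_parse_error(sprintf("duplicate site '%s' in agent signature", nm),
                       nm_tok$line, nm_tok$col)
    }
    values <- NULL
    if (cur_type(st) == "colon") {
      advance(st)
      expect(st, "lparen", "'('")
      values <- character()
      while (cur_type(st) %in% c("ident", "number")) {
        values <- c(values, advance(st)$value)
      }
      expect(st, "rparen", "')'")
      if (length(values) == 0L) {
        lbsk_parse_error("a site type needs at least one internal state value",
                         nm_tok$line, nm_tok$col)
      }
    }
    sig[[nm]] <- values %||% c("u", "p")
    if (cur_type(st) == "comma") advance(st) else break
  }
  if (cur_type(st) != "rbrace") {
    lbsk_parse_error("unbalanced '{' in agent signature", open$line, open$col)
  }
  advance(st)
  sig
}

# Annotation on module parameters: P1{f:(0 1)}-P2{f}-... or {m} or a bare name.
parse_annotation <- function(st) {
  items <- list(parse_ann_item(st))
  while (cur_type(st) == "dash") {
    advance(st)
    items[[length(items) + 1L]] <- parse_ann_item(st)
  }
  items
}

parse_ann_item <- function(st) {
  name <- NULL
  if (cur_type(st) == "ident") name <- advance(st)$value
  sites <- list()
  if (cur_type(st) == "lbrace") {
    open <- advance(st)
    while (cur_type(st) != "rbrace") {
      nm <- expect(st, "ident", "site name")$value
      type <- NULL
      if (cur_type(st) == "colon") {
        advance(st)
        expect(st, "lparen", "'('")
        type <- character()
        while (cur_type(st) %in% c("ident", "number")) {
          type <- c(type, advance(st)$value)
        }
        expect(st, "rparen", "')'")
      }
      sites[[length(sites) + 1L]] <- list(name = nm, type = type)
      if (cur_type(st) == "comma") advance(st) else break
    }
    if (cur_type(st) != "rbrace") {
      lbsk_parse_error("unbalanced '{' in annotation", open$line, open$col)
    }
    advance(st)
  }
  if (is.null(name) && length(sites) == 0L) {
    tk <- cur(st)
    lbsk_parse_error("empty annotation item", tk$line, tk$col)
  }
  ann_item(name, sites)
}

# --- module invocation -------------------------------------------------------

parse_invocation <- function(st) {
  id <- expect(st, "ident", "module identifier")$value
  expect(st, "lparen", "'('")
  actuals <- list()
  while (cur_type(st) != "rparen") {
    actuals[[length(actuals) + 1L]] <- parse_actual(st)
    if (cur_type(st) == "comma") advance(st) else break
  }
  expect(st, "rparen", "')'")
  ast_invoke(id, actuals)
}

parse_actual <- function(st) {
  if (cur_type(st) == "number" ||
      (cur_type(st) == "ident" && peek_type(st) %in% c("star", "slash"))) {
    return(actual_rate(parse_rate_expr(st)))
  }
  expr <- parse_agent_or(st)
  if (cur_type(st) == "colon") {
    advance(st)
    return(actual_agent(expr, parse_annotation(st)))
  }
  if (expr$kind == "ident") return(actual_ident(expr$id))
  if (expr$kind == "literal") {
    # `phosphorylate(Raf{x}, ...)` abbreviates `Raf{x} : Raf{x-site-names}`
    sites <- lapply(expr$sites, function(s) list(name = s$name, type = NULL))
    return(actual_agent(expr, list(ann_item(expr$id, sites))))
  }
  actual_agent(expr, NULL)
}

# --- rate expressions --------------------------------------------------------

parse_rate_expr <- function(st) {
  left <- parse_rate_atom(st)
  while (cur_type(st) %in% c("star", "slash")) {
    op <- if (advance(st)$type == "star") "*" else "/"
    left <- rate_binop(op, left, parse_rate_atom(st))
  }
  left
}

parse_rate_atom <- function(st) {
  type <- cur_type(st)
  if (type == "number") return(rate_const(as.numeric(advance(st)$value)))
  if (type == "ident") return(rate_ident(advance(st)$value))
  tk <- cur(st)
  lbsk_parse_error("expected a rate constant or rate identifier",
                   tk$line, tk$col)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
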