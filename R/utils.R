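# internal graph helpers shared across modules

# cycle test on an edge list given as parallel parent/child character vectors
.hasCycle <- function(parent, child) {
  nodes <- unique(c(parent, child))
  adj <- split(child, factor(parent, levels = nodes))
  state <- setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  visit <- function(v) {
    state[[v]] <<- 1L
    for (w in adj[[v]]) {
      if (state[[w]] == 1L) return(TRUE)
      if (state[[w]] == 0L && visit(w)) return(TRUE)
    }
    state[[v]] <<- 2L
    FALSE
  }
  for (v in nodes) if (state[[v]] == 0L && visit(v)) return(TRUE)
  FALSE
}

# boolean transitive closure (reachability by >=1 step) of a logical adjacency
.reachability <- function(adj) {
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# "parent->child" keys used throughout for candidate edges
.edgeKey <- function(parent, child) paste(parent, child, sep = "->")

# run code with a temporary RNG stream, restoring the caller's state
.withPreservedRNG <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# lossless text encoding of doubles for JSON checkpoints
.num2chr <- function(x) sprintf("%.17g", x)
.chr2num <- function(x) as.numeric(x)
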