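# Rectangular linear assignment by shortest augmenting paths (the
# Jonker-Volgenant scheme, O(n^2 m)). Forbidden assignments are Inf; the
# caller guarantees feasibility (the tracking cost matrices always embed
# finite no-link alternatives). Returns, for each row, the assigned column.

.lap_solve <- function(cost) {
  stopifnot(is.matrix(cost))
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost)
    transposed <- TRUE
  }
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n); v <- numeric(m)
  col4row <- rep(NA_integer_, n)
  row4col <- rep(NA_integer_, m)
  for (cur_row in seq_len(n)) {
    shortest <- rep(Inf, m)
    path <- rep(NA_integer_, m)
    SR <- logical(n); SC <- logical(m)
    minVal <- 0
    i <- cur_row
    sink <- NA_integer_
    while (is.na(sink)) {
      SR[i] <- TRUE
      cols <- which(!SC)
      r <- minVal + cost[i, cols] - u[i] - v[cols]
      upd <- r < shortest[cols]
      shortest[cols[upd]] <- r[upd]
      path[cols[upd]] <- i
      j <- cols[which.min(shortest[cols])]
      minVal <- shortest[j]
      if (!is.finite(minVal)) stop("infeasible assignment problem")
      if (is.na(row4col[j])) {
        sink <- j
      } else {
        SC[j] <- TRUE
        i <- row4col[j]
      }
    }
    u[cur_row] <- u[cur_row] + minVal
    sr <- which(SR)
    sr <- sr[sr != cur_row]
    if (length(sr)) u[sr] <- u[sr] + minVal - shortest[col4row[sr]]
    sc <- which(SC)
    if (length(sc)) v[sc] <- v[sc] - (minVal - shortest[sc])
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      j <- tmp
      if (i == cur_row) break
    }
  }
  if (transposed) {
    out <- rep(NA_integer_, m)
    out[col4row] <- seq_len(n)
    out
  } else {
    col4row
  }
}

# Gated frame-to-frame (or end-to-start) matching: squared-distance costs
# inside the gate, a constant alternative cost b = (1.05 * gate)^2 for
# leaving a point unmatched (the standard linear-assignment tracking
# construction: an (n + m) square matrix whose top-left block holds link
# costs, whose diagonal top-right / bottom-left blocks hold b, and whose
# bottom-right block is free). Returns an integer vector: for each source
# point the matched target index, NA if unmatched.
.lap_match <- function(cost_links, gate) {
  n <- nrow(cost_links); m <- ncol(cost_links)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  b <- (1.05 * gate)^2
  big <- Inf
  C <- matrix(big, n + m, n + m)
  C[seq_len(n), seq_len(m)] <- cost_links
  C[cbind(seq_len(n), m + seq_len(n))] <- b
  C[cbind(n + seq_len(m), seq_len(m))] <- b
  C[n + seq_len(m), m + seq_len(n)] <- 0
  sol <- .lap_solve(C)
  match <- sol[seq_len(n)]
  match[match > m] <- NA_integer_
  match
}
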