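# Brute-force oracle for the dip statistic: direct minimisation of
# sup_t |F_n(t) - G(t)| over unimodal CDFs G.
#
# A unimodal CDF is convex left of its (single) mode and concave right of it;
# a jump is allowed only at the mode.  The optimal G can be taken piecewise
# linear with knots at the distinct data values, and the mode can be taken
# either in a gap between consecutive values (at one of the two endpoint
# limits) or exactly at a data value.  Each such case is a small linear
# program in the fitted CDF values plus the band half-width d; the dip is the
# minimum of the LP optima over all cases.  Solutions of the relaxed LP
# always extend to genuine CDFs reaching 0 and 1 in the tails (a flat
# boundary run can be tilted without leaving the constraint bands), so no
# tail constraints are needed.
#
# The LPs are solved in one batch by scipy's HiGHS solver through the
# bundled inst/oracle/lp_solve.py helper; hand-rolled and boot::simplex
# solvers proved numerically unreliable on the degenerate systems that arise
# here.  Intended for small n (exhaustive checking at n <= 12).

oracle_python_script <- function() {
  p <- system.file("oracle", "lp_solve.py", package = "methvar")
  if (nzchar(p) && file.exists(p)) return(p)
  p <- testthat::test_path("..", "..", "inst", "oracle", "lp_solve.py")
  normalizePath(p, mustWork = TRUE)
}

# All candidate-case LPs for one sample.  Each problem is
# list(c, A, dir, b) minimising c'x s.t. A x (dir) b, x >= 0;
# the band half-width d is always the last variable.
dip_oracle_problems <- function(x) {
  stopifnot(all(is.finite(x)))
  x <- sort(x)
  n <- length(x)
  v <- unique(x)
  m <- length(v)
  Fj <- cumsum(tabulate(match(x, v), m)) / n
  Cj <- c(0, Fj[-m])

  cons_env <- new.env()
  row <- function(nvar) numeric(nvar + 1)

  left_part_cons <- function(idx, var_of, nvar) {
    cons <- list()
    for (j in idx) {
      r <- row(nvar); r[var_of[j]] <- 1; r[nvar + 1] <- -1
      cons[[length(cons) + 1L]] <- list(coef = r, dir = "<=", rhs = Cj[j])
      r <- row(nvar); r[var_of[j]] <- 1; r[nvar + 1] <- 1
      cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = Fj[j])
    }
    if (length(idx) >= 2) {
      for (k in seq_len(length(idx) - 1L)) {
        j1 <- idx[k]; j2 <- idx[k + 1L]
        r <- row(nvar); r[var_of[j2]] <- 1; r[var_of[j1]] <- -1
        cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
      }
    }
    if (length(idx) >= 3) {
      for (k in 2:(length(idx) - 1L)) {
        jm <- idx[k - 1L]; j0 <- idx[k]; jp <- idx[k + 1L]
        dv0 <- v[j0] - v[jm]; dv1 <- v[jp] - v[j0]
        r <- row(nvar)
        r[var_of[jp]] <- dv0; r[var_of[j0]] <- -(dv0 + dv1); r[var_of[jm]] <- dv1
        cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
      }
    }
    cons
  }
  right_part_cons <- function(idx, var_of, nvar, jump_at_first = FALSE) {
    cons <- list()
    for (j in idx) {
      up <- if (jump_at_first && j == idx[1L]) Fj[j] else Cj[j]
      r <- row(nvar); r[var_of[j]] <- 1; r[nvar + 1] <- -1
      cons[[length(cons) + 1L]] <- list(coef = r, dir = "<=", rhs = up)
      r <- row(nvar); r[var_of[j]] <- 1; r[nvar + 1] <- 1
      cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = Fj[j])
      r <- row(nvar); r[var_of[j]] <- 1
      cons[[length(cons) + 1L]] <- list(coef = r, dir = "<=", rhs = 1)
    }
    if (length(idx) >= 2) {
      for (k in seq_len(length(idx) - 1L)) {
        j1 <- idx[k]; j2 <- idx[k + 1L]
        r <- row(nvar); r[var_of[j2]] <- 1; r[var_of[j1]] <- -1
        cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
      }
    }
    if (length(idx) >= 3) {
      for (k in 2:(length(idx) - 1L)) {
        jm <- idx[k - 1L]; j0 <- idx[k]; jp <- idx[k + 1L]
        dv0 <- v[j0] - v[jm]; dv1 <- v[jp] - v[j0]
        r <- row(nvar)
        r[var_of[j0]] <- dv0 + dv1; r[var_of[jm]] <- -dv1; r[var_of[jp]] <- -dv0
        cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
      }
    }
    cons
  }

  problems <- list()
  add_problem <- function(nvar, cons) {
    A <- do.call(rbind, lapply(cons, `[[`, "coef"))
    problems[[length(problems) + 1L]] <<- list(
      c = c(rep(0, nvar), 1),
      A = A,
      dir = vapply(cons, `[[`, character(1), "dir"),
      b = vapply(cons, `[[`, numeric(1), "rhs"))
  }

  if (m == 1L) {
    # all values tied: a point mass fits exactly up to the half-count
    return(list(problems = list(), floor_value = 1 / (2 * n)))
  }

  add_problem(m, right_part_cons(1:m, seq_len(m), m))  # mode below all data
  add_problem(m, left_part_cons(1:m, seq_len(m), m))   # mode above all data

  for (a in seq_len(m - 1L)) {
    gl <- 1:a; gr <- (a + 1L):m
    var_of <- integer(m); var_of[gl] <- seq_along(gl)
    var_of[gr] <- length(gl) + seq_along(gr)

    ## mode just right of v_a: extra var h0 = G at the mode
    nvar <- m + 1L; h0 <- m + 1L
    cons <- c(left_part_cons(gl, var_of, nvar),
              right_part_cons(gr, var_of, nvar))
    r <- row(nvar); r[h0] <- 1; r[var_of[a]] <- -1
    cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
    r <- row(nvar); r[h0] <- 1; r[nvar + 1] <- 1
    cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = Fj[a])
    r <- row(nvar); r[h0] <- 1; r[nvar + 1] <- -1
    cons[[length(cons) + 1L]] <- list(coef = r, dir = "<=", rhs = Fj[a])
    r <- row(nvar); r[var_of[a + 1L]] <- 1; r[h0] <- -1
    cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
    if (a + 2L <= m) {
      dv_gap <- v[a + 1L] - v[a]; dv_next <- v[a + 2L] - v[a + 1L]
      r <- row(nvar)
      r[var_of[a + 1L]] <- dv_next + dv_gap
      r[h0] <- -dv_next; r[var_of[a + 2L]] <- -dv_gap
      cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
    }
    add_problem(nvar, cons)

    ## mode just left of v_{a+1}: extra var ge = G(mode-) there
    nvar <- m + 1L; ge <- m + 1L
    cons <- c(left_part_cons(gl, var_of, nvar),
              right_part_cons(gr, var_of, nvar))
    r <- row(nvar); r[ge] <- 1; r[var_of[a]] <- -1
    cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
    r <- row(nvar); r[ge] <- 1; r[nvar + 1] <- -1
    cons[[length(cons) + 1L]] <- list(coef = r, dir = "<=", rhs = Fj[a])
    r <- row(nvar); r[var_of[a + 1L]] <- 1; r[ge] <- -1
    cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
    if (a >= 2L) {
      dv_prev <- v[a] - v[a - 1L]; dv_gap <- v[a + 1L] - v[a]
      r <- row(nvar)
      r[ge] <- dv_prev; r[var_of[a]] <- -(dv_prev + dv_gap)
      r[var_of[a - 1L]] <- dv_gap
      cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
    }
    add_problem(nvar, cons)
  }

  ## mode exactly at data value v_a (jump there)
  for (a in seq_len(m)) {
    gl <- if (a >= 2L) 1:(a - 1L) else integer(0)
    gr <- a:m
    var_of <- integer(m); var_of[gl] <- seq_along(gl)
    var_of[gr] <- length(gl) + seq_along(gr)
    has_ext <- length(gl) >= 1L
    nvar <- m + as.integer(has_ext)
    cons <- right_part_cons(gr, var_of, nvar, jump_at_first = TRUE)
    if (has_ext) {
      ge <- m + 1L
      cons <- c(cons, left_part_cons(gl, var_of, nvar))
      r <- row(nvar); r[ge] <- 1; r[var_of[a - 1L]] <- -1
      cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
      r <- row(nvar); r[ge] <- 1; r[nvar + 1] <- -1
      cons[[length(cons) + 1L]] <- list(coef = r, dir = "<=", rhs = Cj[a])
      r <- row(nvar); r[var_of[a]] <- 1; r[ge] <- -1
      cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
      if (a >= 3L) {
        dv_prev <- v[a - 1L] - v[a - 2L]; dv_gap <- v[a] - v[a - 1L]
        r <- row(nvar)
        r[ge] <- dv_prev; r[var_of[a - 1L]] <- -(dv_prev + dv_gap)
        r[var_of[a - 2L]] <- dv_gap
        cons[[length(cons) + 1L]] <- list(coef = r, dir = ">=", rhs = 0)
      }
    }
    add_problem(nvar, cons)
  }

  list(problems = problems, floor_value = NULL)
}

# Batched oracle: one python/scipy invocation for a list of samples.
dip_oracle_many <- function(samples) {
  built <- lapply(samples, dip_oracle_problems)
  all_problems <- list()
  index <- vector("list", length(samples))
  for (i in seq_along(built)) {
    np <- length(built[[i]]$problems)
    index[[i]] <- if (np) length(all_problems) + seq_len(np) else integer(0)
    all_problems <- c(all_problems, built[[i]]$problems)
  }
  values <- numeric(0)
  if (length(all_problems)) {
    fin <- tempfile(fileext = ".json")
    fout <- tempfile(fileext = ".json")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    jsonlite::write_json(
      list(problems = lapply(all_problems, function(p)
        list(c = p$c, A = p$A, dir = p$dir, b = p$b))),
      fin, digits = NA, auto_unbox = FALSE, matrix = "rowmajor")
    status <- system2("python", c(oracle_python_script(), fin, fout))
    stopifnot(status == 0L)
    out <- jsonlite::read_json(fout, simplifyVector = TRUE)
    values <- vapply(out$values, function(vv)
      if (is.null(vv) || is.na(vv)) Inf else as.numeric(vv), numeric(1))
  }
  vapply(seq_along(samples), function(i) {
    if (!is.null(built[[i]]$floor_value)) return(built[[i]]$floor_value)
    min(values[index[[i]]])
  }, numeric(1))
}

dip_oracle <- function(x) dip_oracle_many(list(x))
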