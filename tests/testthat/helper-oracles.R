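# Independent brute-force oracles, kept deliberately naive.

# All unordered node pairs within both radii, by explicit distance matrix.
# Node id is row-major from 1: (row, col) = ((id-1) %/% side, (id-1) %% side).
brute_pairs <- function(side, r0, radii) {
  n <- side * side
  row <- (seq_len(n) - 1) %/% side
  col <- (seq_len(n) - 1) %% side
  d2 <- outer(row, row, "-")^2 + outer(col, col, "-")^2
  rmin2 <- pmin(outer(radii, radii, pmin), r0)^2
  ok <- d2 <= rmin2 & upper.tri(d2)
  sum(ok)
}

# Neighbour count of one node by offset enumeration.
brute_neighbours <- function(side, r0, row, col) {
  rmax <- floor(r0)
  cnt <- 0
  for (dx in -rmax:rmax) for (dy in -rmax:rmax) {
    if (dx == 0 && dy == 0) next
    if (dx * dx + dy * dy > r0 * r0) next
    tr <- row + dx; tc <- col + dy
    if (tr >= 0 && tr < side && tc >= 0 && tc < side) cnt <- cnt + 1
  }
  cnt
}

# Full-contact undirected pair count on a bounded side x side lattice:
# sum over signed offsets (dx,dy) != (0,0) with dx^2+dy^2 <= r0^2 of
# (side-|dx|)(side-|dy|), halved. Closed form independent of the edge list.
offset_pair_count <- function(side, r0) {
  rmax <- floor(r0)
  total <- 0
  for (dx in -rmax:rmax) for (dy in -rmax:rmax) {
    if (dx == 0 && dy == 0) next
    if (dx * dx + dy * dy > r0 * r0) next
    total <- total + (side - abs(dx)) * (side - abs(dy))
  }
  total / 2
}

# Hand-built trace tibble: one game with given day rows.
make_trace <- function(participant_id, game_index, loads, radii,
                       end_condition = "timeout") {
  tibble::tibble(
    participant_id = as.integer(participant_id),
    game_index = as.integer(game_index),
    day = seq_along(loads),
    infection_load = loads,
    radius = radii,
    contacts = 0L,
    points = 0L,
    end_condition = end_condition
  )
}

# Noise-free trace following the response curve exactly at constant alpha.
response_trace <- function(participant_id, game_index, loads, alpha, r0 = 4) {
  make_trace(participant_id, game_index, loads,
             response_radius(loads, alpha, r0))
}

# Marginal log-likelihood of the one-way random-intercept normal model
# (participant intercepts), evaluated directly from the per-group
# closed form. Independent of lme4.
oneway_loglik <- function(y, group, mu, sigma_b, sigma_e) {
  ll <- 0
  for (g in unique(group)) {
    yg <- y[group == g]
    ng <- length(yg)
    v <- sigma_e^2 + ng * sigma_b^2
    ssw <- sum((yg - mean(yg))^2)
    ll <- ll - 0.5 * (ng * log(2 * pi) + (ng - 1) * log(sigma_e^2) +
                        log(v) + ssw / sigma_e^2 +
                        ng * (mean(yg) - mu)^2 / v)
  }
  ll
}
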