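# Shared fixtures: all built in code, no files beyond the packaged ones.

# Life table with no mortality at all, ages 65-120.
zero_mortality_lt <- function(sex = "female") {
  life_table(65:120, rep(0, 56), sex = sex)
}

# Minimal valid parameter set built around the published cost/utility
# structure, with every transition probability set explicitly (identical in
# all age bands) and all relative risks 1 unless overridden, so the three
# strategies share the SB-THA probability row.
toy_params <- function(p_dis = 0, p_revdis = 0, p_revnondis = 0,
                       rr = rep(1, 6), u_well = c(0.820, 0.870, 0.870),
                       du = c(-0.110, -0.185, -0.287),
                       costs = c(c_dislocation = 220679, c_implant_bha = 572000,
                                 c_implant_sb = 611000, c_implant_dm = 714000,
                                 fee_bha = 195000, fee_tha = 376900,
                                 fee_rtha = 548100, c_initial_bha = 2122628,
                                 c_initial_tha = 2191285, c_well_annual = 1399413)) {
  bands <- c("65_69", "70_74", "75_79", "80_84", "85_89")
  prob <- function(stub, p) data.frame(name = paste0(stub, "_", bands),
                                       point = p, role = "probability")
  tb <- rbind(
    prob("p_dis_sb", p_dis), prob("p_revdis_sb", p_revdis),
    prob("p_revnondis_sb", p_revnondis),
    data.frame(name = c("rr_dis_dm_sb", "rr_dis_dm_bha", "rr_revdis_bha_dm",
                        "rr_revnondis_bha_dm", "rr_revdis_dm_sb",
                        "rr_revnondis_dm_sb"),
               point = rr, role = "rr"),
    data.frame(name = c("du_dis", "du_rtha", "du_rrtha"), point = du,
               role = "disutility"),
    data.frame(name = c("u_well_bha", "u_well_sb", "u_well_dm"),
               point = u_well, role = "utility"),
    data.frame(name = c("u_well_rtha", "u_well_rrtha"),
               point = c(max(0, u_well[3] + du[2]), max(0, u_well[3] + du[3])),
               role = "utility"),
    data.frame(name = "u_dead", point = 0, role = "utility"),
    data.frame(name = names(costs), point = unname(costs), role = "cost"))
  tb$low <- tb$point
  tb$high <- tb$point
  cea_parameters(tb)
}

# Parameter set in which the three strategies are indistinguishable.
identical_strategy_params <- function(...) {
  toy_params(...,
             costs = c(c_dislocation = 220679, c_implant_bha = 600000,
                       c_implant_sb = 600000, c_implant_dm = 600000,
                       fee_bha = 300000, fee_tha = 300000, fee_rtha = 548100,
                       c_initial_bha = 2000000, c_initial_tha = 2000000,
                       c_well_annual = 1399413),
             u_well = c(0.85, 0.85, 0.85))
}

# Discounted annuity factor sum_{t=1..h} (1+r)^-(t-1).
annuity <- function(h, r) sum((1 + r)^-(seq_len(h) - 1))

# Brute-force enumeration oracle for a two-cycle run with zero mortality,
# default cycle semantics, a single strategy. Walks the complete outcome
# tree with plain arithmetic, independently of the package's engines.
enumerate_two_cycles <- function(v, strategy, r = 0.02) {
  stopifnot(strategy == "SB_THA")  # rr-free arm keeps the oracle simple
  p_dis <- v[["p_dis_sb_75_79"]]
  p_rn <- v[["p_revnondis_sb_75_79"]]
  u <- v[["u_well_sb"]]
  u_rt <- v[["u_well_rtha"]]
  du_r <- v[["du_rtha"]]
  bundle <- v[["c_initial_tha"]] + v[["c_implant_sb"]] + v[["fee_tha"]]
  maint <- v[["c_well_annual"]]
  crev <- v[["fee_rtha"]] + v[["c_implant_dm"]] + v[["c_initial_tha"]]
  cdis <- v[["c_dislocation"]]
  df2 <- 1 / (1 + r)
  # cycle-1 branches from (WELL, tracker 0)
  paths <- list(
    # revision non-dislocation, then (R-THA implant = DM row; rr = 1)
    list(p = p_rn, c1 = bundle + crev, u1 = u + du_r, state = "rt"),
    list(p = p_dis, c1 = bundle + cdis, u1 = u + v[["du_dis"]], state = "well1"),
    list(p = 1 - p_rn - p_dis, c1 = bundle, u1 = u, state = "well0"))
  total_c <- 0
  total_q <- 0
  for (pt in paths) {
    # cycle-2 branches given the cycle-1 outcome
    p_rd_dm <- v[["p_revdis_sb_75_79"]] * v[["rr_revdis_dm_sb"]]
    p_rn_dm <- p_rn * v[["rr_revnondis_dm_sb"]]
    p_dis_dm <- p_dis * v[["rr_dis_dm_sb"]]
    br <- switch(pt$state,
      rt = list(  # on the revised implant; first dislocation reduces
        list(p = p_rn_dm + p_rd_dm, c2 = maint + crev, u2 = u_rt + v[["du_rrtha"]]),
        list(p = p_dis_dm, c2 = maint + cdis, u2 = u_rt + v[["du_dis"]]),
        list(p = 1 - p_rn_dm - p_rd_dm - p_dis_dm, c2 = maint, u2 = u_rt)),
      well1 = list(  # tracker 1: second dislocation revises
        list(p = p_rn + p_dis, c2 = maint + crev, u2 = u + du_r),
        list(p = 1 - p_rn - p_dis, c2 = maint, u2 = u)),
      well0 = list(
        list(p = p_rn, c2 = maint + crev, u2 = u + du_r),
        list(p = p_dis, c2 = maint + cdis, u2 = u + v[["du_dis"]]),
        list(p = 1 - p_rn - p_dis, c2 = maint, u2 = u)))
    for (b in br) {
      w <- pt$p * b$p
      total_c <- total_c + w * (pt$c1 + df2 * b$c2)
      total_q <- total_q + w * (max(0, pt$u1) + df2 * max(0, b$u2))
    }
  }
  c(cost = total_c, qaly = total_q)
}
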