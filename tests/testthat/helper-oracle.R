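# Independent reference integrations used as oracles.
#
# The adaptive-step solver below (deSolve::lsoda with event-based conductance
# jumps and root-triggered resets) shares no code with the package's
# fixed-step integrator.

# Adaptive-step integration of the AdEx + two-conductance-channel ODEs.
# input: data.frame(time, weight, receptor) of presynaptic events.
# Returns list(times, v, w, spikes).
ode_oracle <- function(p, duration, input = NULL, v0 = NULL,
                       times = NULL, rtol = 1e-10, atol = 1e-10) {
  testthat::skip_if_not_installed("deSolve")
  v0 <- v0 %||% p$e_l
  times <- times %||% seq(0, duration, by = 0.01)
  deriv <- function(t, y, parms) {
    v <- y[1]; w <- y[2]; ge <- y[3]; gi <- y[4]
    i_exp <- if (p$delta_t > 0) {
      p$g_l * p$delta_t * exp(min((v - p$v_t) / p$delta_t, 16))
    } else {
      0
    }
    dv <- (-p$g_l * (v - p$e_l) + i_exp - ge * (v - p$e_e) -
             gi * (v - p$e_i) - w + p$i_ext) / (p$c_m * 1000)
    dw <- (p$a * (v - p$e_l) - w) / p$tau_w
    list(c(dv, dw, -ge / p$tau_e, -gi / p$tau_i))
  }
  spikes <- numeric()
  thr <- if (p$delta_t > 0) p$v_spike else p$v_t

  ev_times <- if (!is.null(input)) sort(unique(input$time)) else numeric()
  eventfun <- function(t, y, parms) {
    hit <- which(!is.na(match(input$time, t)))
    for (i in hit) {
      ch <- if (input$receptor[i] == "exc") 3 else 4
      y[ch] <- y[ch] + input$weight[i]
    }
    y
  }
  rootfun <- function(t, y, parms) y[1] - thr
  resetfun <- function(t, y, parms) {
    spikes <<- c(spikes, t)
    y[1] <- p$v_reset
    y[2] <- y[2] + p$b
    y
  }
  # integrate piecewise between threshold crossings, applying reset and a
  # refractory clamp by restarting after tau_ref
  y <- c(v0, 0, 0, 0)
  t_cur <- 0
  out_t <- c(); out_v <- c(); out_w <- c()
  repeat {
    seg_times <- unique(c(t_cur, times[times > t_cur & times <= duration],
                          duration))
    ev <- if (length(ev_times)) {
      evs <- ev_times[ev_times > t_cur & ev_times <= duration]
      if (length(evs)) {
        seg_times <- sort(unique(c(seg_times, evs)))
        list(func = eventfun, time = evs, root = FALSE)
      } else {
        NULL
      }
    } else {
      NULL
    }
    args <- list(y = y, times = seg_times, func = deriv, parms = NULL,
                 rtol = rtol, atol = atol, maxsteps = 1e6)
    if (!is.null(ev)) {
      args$events <- list(func = ev$func, time = ev$time)
    }
    args$rootfun <- rootfun
    sol <- do.call(deSolve::lsoda, args)
    out_t <- c(out_t, sol[, 1]); out_v <- c(out_v, sol[, 2])
    out_w <- c(out_w, sol[, 3])
    t_end <- sol[nrow(sol), 1]
    if (t_end >= duration - 1e-9) break
    # root hit: spike
    y <- sol[nrow(sol), -1]
    y <- resetfun(t_end, y, NULL)
    # refractory clamp: hold v at reset, decay g and w analytically
    t_out <- min(t_end + p$tau_ref, duration)
    if (p$tau_ref > 0) {
      hold <- times[times > t_end & times <= t_out]
      if (length(hold)) {
        out_t <- c(out_t, hold)
        out_v <- c(out_v, rep(p$v_reset, length(hold)))
        out_w <- c(out_w, (y[2] - p$a * (p$v_reset - p$e_l)) *
                     exp(-(hold - t_end) / p$tau_w) +
                     p$a * (p$v_reset - p$e_l))
      }
      # deliver events that fall inside the refractory window
      if (!is.null(input)) {
        inref <- which(input$time > t_end & input$time <= t_out)
        for (i in inref) {
          ch <- if (input$receptor[i] == "exc") 3 else 4
          y[ch] <- y[ch] + input$weight[i]
          # decay applied below jointly; approximate by decaying from event
        }
      }
      y[3] <- y[3] * exp(-(t_out - t_end) / p$tau_e)
      y[4] <- y[4] * exp(-(t_out - t_end) / p$tau_i)
      wa <- p$a * (p$v_reset - p$e_l)
      y[2] <- wa + (y[2] - wa) * exp(-(t_out - t_end) / p$tau_w)
      y[1] <- p$v_reset
      t_cur <- t_out
    } else {
      t_cur <- t_end
    }
    if (t_cur >= duration - 1e-9) break
  }
  ord <- order(out_t)
  list(times = out_t[ord], v = out_v[ord], w = out_w[ord], spikes = spikes)
}

# Closed-form subthreshold PSP of a LIF neuron (reversal term linearized at
# E_L) for one presynaptic spike of weight w at t = 0:
#   tau_m dV/dt = -(V - E_L) + (w/g_l) e^(-t/tau_s) (E_rev - E_L)
psp_closed_form <- function(p, w, e_rev, tau_s, t) {
  tau_m <- p$c_m / p$g_l * 1000
  drive <- w / p$g_l * (e_rev - p$e_l)
  if (abs(tau_m - tau_s) < 1e-12) {
    p$e_l + drive * t / tau_m * exp(-t / tau_m)
  } else {
    p$e_l + drive * tau_s / (tau_s - tau_m) *
      (exp(-t / tau_s) - exp(-t / tau_m))
  }
}

# Minimal single-neuron network wrapper used across tests.
one_neuron_net <- function(p, sources = 0, syn = NULL, rate = NA_real_,
                           rule = NULL) {
  pops <- tibble::tibble(
    name = c("cell", if (sources > 0) "in"),
    size = c(1L, if (sources > 0) as.integer(sources)),
    cell_type = c("probe", if (sources > 0) "source"),
    params = c(list(p), if (sources > 0) list(NULL)),
    rate = c(NA_real_, if (sources > 0) rate),
    x = list(NULL), y = list(NULL)
  )
  prj <- if (sources > 0) {
    tibble::tibble(label = "in", source = "in", target = "cell",
                   rule = list(rule %||% rule_all()), syn = list(syn),
                   delay = list(delay_constant(1)), external = TRUE)
  } else {
    tibble::tibble(label = character(), source = character(),
                   target = character(), rule = list(), syn = list(),
                   delay = list(), external = logical())
  }
  instantiate_synapses(network_spec(pops, prj), seed = 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
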