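#' Synthetic open-trial configuration
#'
#' Parameters of the synthetic cohort generator. The defaults emulate the
#' uptake pattern of a two-week open trial of a youth well-being chatbot:
#' 393 registrations of whom 238 logged in, roughly half the logins in
#' the 13-24 target age range, 70.9% of target-age users female and 47.2%
#' NZ European, worry scores near mean 5.1 (SD 2.6) before and 4.3
#' (SD 2.5) after a session, 81 of 127 target-age users reaching the
#' outro with 30 completing the recheck, and 31 returning for a repeat
#' session. They are emulation targets for exercising the analytics
#' pipeline, not findings. Only two demographic categories are pinned by
#' those targets; the remaining probability mass is spread over invented
#' filler categories (an explicit `other_unspecified` bucket included).
#'
#' @param n_registered number of portal registrations.
#' @param p_login probability a registration ever logs in (238/393).
#' @param p_target_age probability a login is aged 13-24 (127/238).
#' @param target_age inclusive target age bounds.
#' @param nontarget_age inclusive age bounds for out-of-range users.
#' @param gender_mix,ethnicity_mix named probability vectors (sum to 1)
#'   for target-age demographics.
#' @param mu_pre,sd_pre mean/SD of the latent pre-session worry score;
#'   scores are drawn from this normal truncated to \[0,10\] and rounded
#'   to integers.
#' @param effect_delta mean within-session worry reduction (5.1 - 4.3).
#' @param sd_noise SD of the noise in the post-score model
#'   `post = clamp(round(pre - effect_delta + noise), 0, 10)`.
#' @param p_reach_outro probability a session proceeds to the wrap-up
#'   after an activity (81/127).
#' @param p_complete_outro probability the outro recheck is answered
#'   rather than declined (30/81).
#' @param p_return probability a user comes back for a second session
#'   (31/127).
#' @param seed integer seed for the whole simulation.
#' @return a `trial_config` list.
#' @export
trial_config <- function(n_registered = 393,
                         p_login = 238 / 393,
                         p_target_age = 127 / 238,
                         target_age = c(13, 24),
                         nontarget_age = c(25, 64),
                         gender_mix = c(female = 0.709, male = 0.241,
                                        another_gender = 0.05),
                         ethnicity_mix = c(nz_european = 0.472, maori = 0.22,
                                           pacific = 0.1, asian = 0.12,
                                           other_unspecified = 0.088),
                         mu_pre = 5.1, sd_pre = 2.6,
                         effect_delta = 0.8, sd_noise = 1.5,
                         p_reach_outro = 81 / 127,
                         p_complete_outro = 30 / 81,
                         p_return = 31 / 127,
                         seed = 1L) {
  probs <- c(p_login, p_target_age, p_reach_outro, p_complete_outro, p_return)
  if (any(probs < 0 | probs > 1)) stop_cf("probabilities must lie in [0, 1]")
  if (mu_pre < 0 || mu_pre > 10) stop_cf("mu_pre must lie in [0, 10]")
  if (abs(sum(gender_mix) - 1) > 1e-6 || abs(sum(ethnicity_mix) - 1) > 1e-6)
    stop_cf("gender_mix and ethnicity_mix must each sum to 1")
  structure(list(n_registered = n_registered, p_login = p_login,
                 p_target_age = p_target_age, target_age = target_age,
                 nontarget_age = nontarget_age, gender_mix = gender_mix,
                 ethnicity_mix = ethnicity_mix, mu_pre = mu_pre,
                 sd_pre = sd_pre, effect_delta = effect_delta,
                 sd_noise = sd_noise, p_reach_outro = p_reach_outro,
                 p_complete_outro = p_complete_outro, p_return = p_return,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Read / write a trial configuration as YAML
#' @param path YAML file path.
#' @return a [trial_config()] (read) / `path` (write).
#' @export
read_trial_config <- function(path) {
  doc <- yaml::read_yaml(path)
  doc$gender_mix <- unlist(doc$gender_mix)
  doc$ethnicity_mix <- unlist(doc$ethnicity_mix)
  doc$target_age <- unlist(doc$target_age)
  doc$nontarget_age <- unlist(doc$nontarget_age)
  do.call(trial_config, doc)
}

#' @rdname read_trial_config
#' @param config a [trial_config()].
#' @export
write_trial_config <- function(config, path) {
  doc <- unclass(config)
  doc$gender_mix <- as.list(doc$gender_mix)
  doc$ethnicity_mix <- as.list(doc$ethnicity_mix)
  doc$target_age <- as.list(doc$target_age)
  doc$nontarget_age <- as.list(doc$nontarget_age)
  writeLines(yaml::as.yaml(doc), path, useBytes = TRUE)
  invisible(path)
}

draw_pre_score <- function(cfg) {
  repeat {
    x <- stats::rnorm(1, cfg$mu_pre, cfg$sd_pre)
    if (x >= 0 && x <= 10) return(as.integer(round(x)))
  }
}

draw_post_score <- function(pre, cfg) {
  x <- round(pre - cfg$effect_delta + stats::rnorm(1, 0, cfg$sd_noise))
  as.integer(min(10L, max(0L, x)))
}

# drive one full user session against the engine with sampled choices;
# returns the ended/abandoned session (whose $events carry the usage data)
drive_session <- function(graph, user_id, prior, cfg, registry, lexicon,
                          econf, clock_origin) {
  tr <- start_session(graph, user_id, prior = prior, seed = 0L,
                      registry = registry, lexicon = lexicon, config = econf,
                      clock_origin = clock_origin, check = FALSE)
  menus_seen <- 0L
  free_texts <- c("ok", "all good", "my whanau", "not sure", "getting by")
  pre_this_session <- NA_integer_
  for (i in 1:60) { # hard stop well above any plausible session length
    if (tr$ended) break
    aw <- tr$awaiting
    input <- if (aw$kind == "assessment") {
      in_outro <- identical(graph$nodes[[aw$node_id]]$module_id, "outro")
      if (in_outro) {
        if (!is.na(pre_this_session) &&
            stats::runif(1) < cfg$p_complete_outro)
          ui_score(draw_post_score(pre_this_session, cfg))
        else ui_decline()
      } else {
        pre_this_session <- draw_pre_score(cfg)
        ui_score(pre_this_session)
      }
    } else if (aw$kind == "quick_reply" && identical(aw$node_id, "__menu__")) {
      menus_seen <- menus_seen + 1L
      opts <- setdiff(aw$options, econf$finish_label)
      if (menus_seen == 1L && length(opts)) {
        ui_option(opts[[sample.int(length(opts), 1)]])
      } else if (stats::runif(1) < cfg$p_reach_outro &&
                 econf$finish_label %in% aw$options) {
        ui_option(econf$finish_label)
      } else break # user drifts away mid-session
    } else if (aw$kind == "quick_reply") {
      ui_option(aw$options[[sample.int(length(aw$options), 1)]])
    } else { # free text
      ui_text(free_texts[[sample.int(length(free_texts), 1)]])
    }
    tr <- advance_turn(tr$session, graph, input, registry = registry,
                       lexicon = lexicon, config = econf)
  }
  tr$session
}

#' Simulate a synthetic open trial
#'
#' Generates a reproducible synthetic cohort by *running the actual
#' engine*: registrations are drawn, a subset logs in, and every login's
#' session is produced by replaying the demo graph with sampled menu
#' choices, sampled worry scores (pre from the discretized truncated
#' normal, post from the effect model) and sampled dropout, so the
#' resulting event log has exactly the shape live usage would produce and
#' feeds [summarize_cohort()] / [prepost_summary()] unchanged.
#'
#' @param config a [trial_config()].
#' @param graph content pack to replay (default [build_demo_graph()]).
#' @param registry,lexicon NLU configuration.
#' @return a list with `users` (data.frame: user_id, age, gender,
#'   ethnicity, registered_at) and `log` (an [event_log()]).
#' @export
simulate_trial <- function(config, graph = build_demo_graph(),
                           registry = default_intents(),
                           lexicon = default_risk_lexicon()) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  n <- config$n_registered
  econf <- engine_config()
  if (n == 0)
    return(list(users = data.frame(user_id = character(0), age = integer(0),
                                   gender = character(0),
                                   ethnicity = character(0),
                                   registered_at = character(0)),
                log = event_log()))
  issues <- validate_graph(graph)
  if (any(issues$severity == "error")) stop_cf("simulate_trial: invalid graph")

  draw_cat <- function(mix) names(mix)[sample.int(length(mix), 1, prob = mix)]
  user_id <- sprintf("u%04d", seq_len(n))
  in_target <- stats::runif(n) < config$p_target_age
  age <- ifelse(in_target,
                sample(seq(config$target_age[1], config$target_age[2]), n, TRUE),
                sample(seq(config$nontarget_age[1], config$nontarget_age[2]), n, TRUE))
  gender <- vapply(seq_len(n), function(i) draw_cat(config$gender_mix), "")
  ethnicity <- vapply(seq_len(n), function(i) draw_cat(config$ethnicity_mix), "")
  registered_at <- iso_time((seq_len(n) - 1L) * 900)
  logs_in <- stats::runif(n) < config$p_login

  users <- data.frame(user_id = user_id, age = age, gender = gender,
                      ethnicity = ethnicity, registered_at = registered_at,
                      stringsAsFactors = FALSE)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- list(event(registered_at[i], user_id[i], "registration", list()))
    if (logs_in[i]) {
      origin <- (i - 1L) * 900 + 100
      s1 <- drive_session(graph, user_id[i], NULL, config, registry, lexicon,
                          econf, origin)
      ev <- c(ev, s1$events)
      if (stats::runif(1) < config$p_return) {
        s2 <- drive_session(graph, user_id[i], s1, config, registry, lexicon,
                            econf, origin + 86400)
        ev <- c(ev, s2$events)
      }
    }
    events[[i]] <- ev
  }
  list(users = users, log = event_log(do.call(c, events)))
}
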