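#' Build the demo content pack
#'
#' A complete, validation-clean dialog graph shaped like a real deployed
#' well-being chatbot: an onboarding block (intro with an abbreviated
#' re-entry path, consent, the 0-10 single-item worry assessment,
#' psychoeducation), twelve initial activity modules teaching coping
#' skills, four modules added after launch (flagged `added_post_launch`),
#' and an outro block (assessment recheck, feedback, resources). All
#' dialog text is original placeholder copy — the *structure* is the
#' fixture's claim, not the clinical content. The same graph ships
#' serialized as `extdata/demo_graph.yaml`.
#'
#' @return a `dialog_graph` that passes [validate_graph()] with no issues.
#' @export
build_demo_graph <- function() {
  worry <- function(id, required, to) assessment_node(
    id, "Out of 10, how worried are you about the pandemic right now?",
    item_id = "worry", scale_min = 0, scale_max = 10,
    anchors = c("no worries", "totally freaking out"),
    required = required, to = to)

  intro <- dialog_module(
    "intro", "Intro", "intro_gate", role = "onboarding", nodes = list(
      branch_node("intro_gate", condition("session_index", "gt", 1L),
                  true = "intro_back", false = "intro_first",
                  default = "intro_first"),
      message_node("intro_first",
                   c("Kia ora! I'm a friendly helper for strange times.",
                     "Quick heads-up: I'm a computer program, not a real person.",
                     "Here's me on a good hair day:"),
                   to = "intro_selfie"),
      rich_media_node("intro_selfie",
                      attachment_ref("image", "assets/faux_selfie.png",
                                     caption = "faux selfie"),
                      to = "intro_exit_first"),
      exit_module_node("intro_exit_first", hint = "goto:onboarding"),
      message_node("intro_back", "Kia ora, welcome back! Good to see you again.",
                   to = "intro_exit_back"),
      exit_module_node("intro_exit_back", hint = "goto:brief_assessment")))

  onboarding <- dialog_module(
    "onboarding", "Onboarding", "onb_msg", role = "onboarding", nodes = list(
      message_node("onb_msg",
                   c("I share practical, evidence-based ideas for looking after yourself.",
                     "We'll check in on how you're feeling, then you pick what to try."),
                   to = "onb_consent"),
      quick_replies_node("onb_consent", "Ready to make a start?",
                         c("Let's go" = "onb_exit", "Tell me more" = "onb_more")),
      message_node("onb_more",
                   "Short activities, no lectures. You drive; I suggest.",
                   to = "onb_exit"),
      exit_module_node("onb_exit", hint = "goto:brief_assessment")))

  brief_assessment <- dialog_module(
    "brief_assessment", "Brief assessment", "ba_item", role = "onboarding",
    nodes = list(
      worry("ba_item", required = TRUE, to = "ba_feedback"),
      message_node("ba_feedback",
                   "Thanks for sharing that with me — it helps me help you.",
                   to = "ba_gate"),
      branch_node("ba_gate", condition("session_index", "gt", 1L),
                  true = "ba_exit_menu", false = "ba_exit_intro",
                  default = "ba_exit_intro"),
      exit_module_node("ba_exit_menu", hint = "menu"),
      exit_module_node("ba_exit_intro", hint = "goto:introductory_information")))

  introductory_information <- dialog_module(
    "introductory_information", "Introductory information", "ii_psycho",
    role = "onboarding", nodes = list(
      message_node("ii_psycho",
                   c("Feeling worried in a pandemic is a normal reaction to a not-normal situation.",
                     "Small daily habits make a real difference to how we cope.",
                     "Here's a poster you can keep:"),
                   to = "ii_poster"),
      rich_media_node("ii_poster",
                      attachment_ref("poster", "assets/tips_reduce_stress.png",
                                     caption = "Tips to reduce stress",
                                     saveable = TRUE),
                      to = "ii_feel"),
      free_text_node("ii_feel", "Before we pick an activity — how are you feeling today?",
                     intent_edges = c(sadness = "ii_sad", happiness = "ii_happy",
                                      fear = "ii_support", stress = "ii_support",
                                      anxiety = "ii_support"),
                     fallback = "ii_ok"),
      message_node("ii_sad", "Hey, I'm sorry to hear you're feeling that way.",
                   to = "ii_exit"),
      message_node("ii_happy", "Love that! Let's keep the good vibes going.",
                   to = "ii_exit"),
      message_node("ii_support",
                   "That's really common right now. Let's find something that helps.",
                   to = "ii_exit"),
      message_node("ii_ok", "Thanks for telling me.", to = "ii_exit"),
      exit_module_node("ii_exit", hint = "menu")))

  # small builders for activity-module shapes
  act_msg <- function(id, title, texts, post = FALSE)
    dialog_module(id, title, paste0(id, "_1"), added_post_launch = post,
                  nodes = list(
                    message_node(paste0(id, "_1"), texts, to = paste0(id, "_x")),
                    exit_module_node(paste0(id, "_x"))))
  act_poster <- function(id, title, texts, ref, caption, post = FALSE)
    dialog_module(id, title, paste0(id, "_1"), added_post_launch = post,
                  nodes = list(
                    message_node(paste0(id, "_1"), texts, to = paste0(id, "_p")),
                    rich_media_node(paste0(id, "_p"),
                                    attachment_ref("poster", ref, caption,
                                                   saveable = TRUE),
                                    to = paste0(id, "_x")),
                    exit_module_node(paste0(id, "_x"))))

  activities <- list(
    dialog_module("stay_connected", "Stay connected", "sc_1", nodes = list(
      message_node("sc_1", "Staying in touch keeps our wells full.", to = "sc_q"),
      quick_replies_node("sc_q", "Who could you message today?",
                         c("Friends" = "sc_tip", "Whānau" = "sc_tip")),
      message_node("sc_tip", "Nice — even a two-line text counts.", to = "sc_x"),
      exit_module_node("sc_x"))),
    act_poster("calming_activities", "Calming activities",
               c("Let's slow things down for a minute.",
                 "Try this: breathe in for 4, hold for 4, out for 4."),
               "assets/calm_breathing.png", "Calm breathing"),
    dialog_module("practice_gratitude", "Practice gratitude", "pg_1", nodes = list(
      message_node("pg_1",
                   c("Gratitude points our attention at the good stuff.",
                     "People often mention whānau, or even just decent wifi."),
                   to = "pg_prompt"),
      free_text_node("pg_prompt", "What's one thing you're grateful for today?",
                     fallback = "pg_ack"),
      message_node("pg_ack", "That's a great one. Hold onto it.", to = "pg_mark"),
      update_value_node("pg_mark", "gratitude_done", value = 1L, to = "pg_x"),
      exit_module_node("pg_x"))),
    act_msg("spirituality", "Spirituality",
            "Whatever grounds you — karakia, prayer, quiet — make a little room for it."),
    act_poster("distract_yourself", "Distract yourself",
               "A good distraction is a legitimate coping tool.",
               "assets/distraction_ideas.png", "Distraction ideas"),
    dialog_module("get_active", "Get active", "ga_1", nodes = list(
      message_node("ga_1", "Moving your body shifts your mood.", to = "ga_q"),
      quick_replies_node("ga_q", "How does a 10-minute walk sound?",
                         c("\U0001F60A" = "ga_ack", "\U0001F610" = "ga_ack",
                           "\U0001F61E" = "ga_ack")),
      message_node("ga_ack", "Noted! Start tiny if you need to.", to = "ga_x"),
      exit_module_node("ga_x"))),
    act_msg("get_expert_help", "Get expert help",
            c("Sometimes the strongest move is asking a human for help.",
              "Your GP, a counsellor, or a free helpline are all good doors.")),
    act_poster("general_tips", "General tips",
               "A few all-purpose ideas that help most people most days.",
               "assets/general_tips.png", "General tips"),
    act_msg("self_care", "Self-care",
            "Basics first: kai, water, shower, sunlight. Boring and powerful."),
    dialog_module("have_a_routine", "Have a routine", "hr_1", nodes = list(
      message_node("hr_1", "Routines give shapeless days a shape.", to = "hr_mark"),
      update_value_node("hr_mark", "routine_seen", value = 1L, to = "hr_x"),
      exit_module_node("hr_x"))),
    act_msg("protect_your_sleep", "Protect your sleep",
            "Same bedtime, dim screens, and let your brain wind down."),
    act_msg("alcohol_and_drugs", "Alcohol and drugs",
            "Substances can feel like a shortcut out of stress, but they borrow from tomorrow."),
    # post-launch additions
    act_msg("money_worries", "Money worries",
            "Money stress is real stress. Small plans beat big panic.", post = TRUE),
    act_msg("anger_management", "Anger management",
            "Anger is information. Let's find the message without the explosion.",
            post = TRUE),
    act_msg("violence", "Violence",
            c("If home doesn't feel safe, that is never your fault.",
              "Talking to someone you trust, or a support line, is a strong first step."),
            post = TRUE),
    dialog_module("pm_message", "Prime Minister's message", "pmm_1",
                  added_post_launch = TRUE, nodes = list(
      rich_media_node("pmm_1",
                      attachment_ref("webview", "assets/pm_top_tips.html",
                                     caption = "Top tips for managing stress"),
                      to = "pmm_2"),
      message_node("pmm_2", "Tap through each tip at your own pace.", to = "pmm_x"),
      exit_module_node("pmm_x"))))

  outro <- dialog_module(
    "outro", "Outro", "out_recheck", role = "outro", nodes = list(
      worry("out_recheck", required = FALSE, to = "out_feedback"),
      quick_replies_node("out_feedback", "How was our chat today?",
                         c("\U0001F60A" = "out_thanks", "\U0001F610" = "out_thanks",
                           "\U0001F61E" = "out_thanks")),
      message_node("out_thanks",
                   c("Thanks heaps for hanging out with me.",
                     "Remember to check in on your hauora — and if things feel heavy, real people can help: your GP, a counsellor, or a free helpline.",
                     "Ka kite! Come back any time."),
                   to = "out_x"),
      exit_module_node("out_x", hint = "end")))

  dialog_graph(
    "demo_wellbeing",
    modules = c(list(intro, onboarding, brief_assessment,
                     introductory_information),
                activities, list(outro)),
    entry_module = "intro",
    priority_bindings = c(self_harm = "get_expert_help_1",
                          abuse_risk = "violence_1",
                          low_mood = "get_expert_help_1",
                          fear = "calming_activities_1",
                          boredom = "distract_yourself_1",
                          quit_exit = "out_recheck"),
    metadata = list(title = "Demo well-being companion", version = "1.0",
                    locale = "en-NZ"))
}
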