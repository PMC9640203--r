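#' The default intent registry
#'
#' Forty distinct intents, granular enough to discern the main
#' mood/emotion states: the eight named emotion intents (anger, sadness,
#' loneliness, stress, fear, anxiety, happiness, excitement), six priority
#' intents recognized anywhere in the dialog (self-harm, risk of abuse,
#' low mood, fear, boredom, quit/exit — fear is both an emotion and a
#' priority), and a tail of everyday conversational intents invented for
#' this fixture. Priority targets resolve inside the demo graph. The same
#' registry ships as `extdata/intents.yaml`.
#'
#' @return an [intent_registry()] of exactly 40 intents.
#' @export
default_intents <- function() {
  p <- function(id, patterns, target)
    intent(id, patterns, is_priority = TRUE, priority_target = target)
  ints <- list(
    # -- named emotion intents --------------------------------------------
    intent("anger", c("angry", "mad", "furious", "so frustrated", "pissed off")),
    intent("sadness", c("sad", "i'm sad", "i'm down", "unhappy", "crying")),
    intent("loneliness", c("lonely", "alone", "no one to talk to", "isolated")),
    intent("stress", c("stressed", "stress", "overwhelmed", "under pressure")),
    intent("anxiety", c("anxious", "anxiety", "worried", "panicking", "freaking out")),
    intent("happiness", c("happy", "great", "really good", "awesome", "choice")),
    intent("excitement", c("excited", "stoked", "can't wait", "hyped")),
    # -- priority intents (recognized anywhere) ---------------------------
    p("fear", c("scared", "afraid", "nervous", "frightened", "terrified"),
      "calming_activities_1"),
    p("self_harm", c("hurting myself", "harming myself", "self harm thoughts"),
      "get_expert_help_1"),
    p("abuse_risk", c("being abused", "someone hits me", "violent at home"),
      "violence_1"),
    p("low_mood", c("depressed", "really low", "low mood", "can't be bothered",
                    "no energy"),
      "get_expert_help_1"),
    p("boredom", c("bored", "boring", "nothing to do", "so dull"),
      "distract_yourself_1"),
    p("quit_exit", c("quit", "exit", "bye", "goodbye", "i'm done", "stop now"),
      "out_recheck"),
    # -- everyday conversational intents (fixture-invented) ---------------
    intent("gratitude", c("grateful", "thankful", "appreciate")),
    intent("sleep", c("can't sleep", "insomnia", "so tired", "exhausted")),
    intent("exercise", c("exercise", "workout", "go for a run")),
    intent("family", c("whanau", "family", "my parents", "my siblings")),
    intent("friends", c("my friends", "my mates", "best friend")),
    intent("school", c("school", "homework", "exams", "ncea")),
    intent("work", c("my job", "work", "my boss", "shifts")),
    intent("money", c("money", "broke", "can't afford", "rent")),
    intent("food", c("food", "kai", "hungry", "snacks")),
    intent("music", c("music", "playlist", "favourite song")),
    intent("games", c("gaming", "video games", "play games")),
    intent("meditation", c("meditate", "meditation", "mindfulness")),
    intent("breathing", c("breathing", "deep breaths", "breathe")),
    intent("lockdown", c("lockdown", "stuck at home", "my bubble", "alert level")),
    intent("pandemic", c("pandemic", "the virus", "getting sick")),
    intent("help", c("help me", "need help", "what can you do")),
    intent("greeting", c("hello", "hi", "kia ora", "hey")),
    intent("thanks", c("thanks", "thank you", "cheers", "ka pai")),
    intent("affirm", c("yes", "yeah", "yep", "sure", "ok")),
    intent("deny", c("nope", "nah", "not really")),
    intent("unsure", c("maybe", "not sure", "don't know", "dunno")),
    intent("weather", c("weather", "raining", "sunny")),
    intent("pets", c("my dog", "my cat", "my pet")),
    intent("humor", c("lol", "haha", "funny", "joke")),
    intent("love", c("love", "my partner", "crush")),
    intent("culture", c("karakia", "marae", "te reo", "matariki")),
    intent("motivation", c("motivation", "can't focus", "procrastinating")))
  intent_registry(ints)
}

#' The default risk lexicon
#'
#' Self-harm phrases trigger the escalation protocol; abuse phrases are
#' routed as a supportive priority digression. Deliberately conservative
#' placeholder phrasing — any deployment must review and localize this
#' list with clinical input. Ships as `extdata/risk_lexicon.yaml`.
#'
#' @return a [risk_lexicon()].
#' @export
default_risk_lexicon <- function() {
  risk_lexicon(
    self_harm = c("kill myself", "hurt myself", "end my life", "suicide",
                  "self harm", "want to die", "better off dead",
                  "end it all"),
    abuse = c("being abused", "abuses me", "hits me", "hit me",
              "not safe at home", "hurts me at home"))
}
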