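fallback_id: fallback
intents:
  - id: anger
    patterns:
      - angry
      - mad
      - furious
      - so frustrated
      - pissed off
  - id: sadness
    patterns:
      - sad
      - i'm sad
      - i'm down
      - unhappy
      - crying
  - id: loneliness
    patterns:
      - lonely
      - alone
      - no one to talk to
      - isolated
  - id: stress
    patterns:
      - stressed
      - stress
      - overwhelmed
      - under pressure
  - id: anxiety
    patterns:
      - anxious
      - anxiety
      - worried
      - panicking
      - freaking out
  - id: happiness
    patterns:
      - happy
      - great
      - really good
      - awesome
      - choice
  - id: excitement
    patterns:
      - excited
      - stoked
      - can't wait
      - hyped
  - id: fear
    patterns:
      - scared
      - afraid
      - nervous
      - frightened
      - terrified
    priority: yes
    target: calming_activities_1
  - id: self_harm
    patterns:
      - hurting myself
      - harming myself
      - self harm thoughts
    priority: yes
    target: get_expert_help_1
  - id: abuse_risk
    patterns:
      - being abused
      - someone hits me
      - violent at home
    priority: yes
    target: violence_1
  - id: low_mood
    patterns:
      - depressed
      - really low
      - low mood
      - can't be bothered
      - no energy
    priority: yes
    target: get_expert_help_1
  - id: boredom
    patterns:
      - bored
      - boring
      - nothing to do
      - so dull
    priority: yes
    target: distract_yourself_1
  - id: quit_exit
    patterns:
      - quit
      - exit
      - bye
      - goodbye
      - i'm done
      - stop now
    priority: yes
    target: out_recheck
  - id: gratitude
    patterns:
      - grateful
      - thankful
      - appreciate
  - id: sleep
    patterns:
      - can't sleep
      - insomnia
      - so tired
      - exhausted
  - id: exercise
    patterns:
      - exercise
      - workout
      - go for a run
  - id: family
    patterns:
      - whanau
      - family
      - my parents
      - my siblings
  - id: friends
    patterns:
      - my friends
      - my mates
      - best friend
  - id: school
    patterns:
      - school
      - homework
      - exams
      - ncea
  - id: work
    patterns:
      - my job
      - work
      - my boss
      - shifts
  - id: money
    patterns:
      - money
      - broke
      - can't afford
      - rent
  - id: food
    patterns:
      - food
      - kai
      - hungry
      - snacks
  - id: music
    patterns:
      - music
      - playlist
      - favourite song
  - id: games
    patterns:
      - gaming
      - video games
      - play games
  - id: meditation
    patterns:
      - meditate
      - meditation
      - mindfulness
  - id: breathing
    patterns:
      - breathing
      - deep breaths
      - breathe
  - id: lockdown
    patterns:
      - lockdown
      - stuck at home
      - my bubble
      - alert level
  - id: pandemic
    patterns:
      - pandemic
      - the virus
      - getting sick
  - id: help
    patterns:
      - help me
      - need help
      - what can you do
  - id: greeting
    patterns:
      - hello
      - hi
      - kia ora
      - hey
  - id: thanks
    patterns:
      - thanks
      - thank you
      - cheers
      - ka pai
  - id: affirm
    patterns:
      - 'yes'
      - yeah
      - yep
      - sure
      - ok
  - id: deny
    patterns:
      - nope
      - nah
      - not really
  - id: unsure
    patterns:
      - maybe
      - not sure
      - don't know
      - dunno
  - id: weather
    patterns:
      - weather
      - raining
      - sunny
  - id: pets
    patterns:
      - my dog
      - my cat
      - my pet
  - id: humor
    patterns:
      - lol
      - haha
      - funny
      - joke
  - id: love
    patterns:
      - love
      - my partner
      - crush
  - id: culture
    patterns:
      - karakia
      - marae
      - te reo
      - matariki
  - id: motivation
    patterns:
      - motivation
      - can't focus
      - procrastinating

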