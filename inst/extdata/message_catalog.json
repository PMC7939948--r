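{
  "greeting": [
    {"id": "greeting-1", "text": "Hey, good to see you again!", "bct_tags": [13]},
    {"id": "greeting-2", "text": "Welcome back! Ready for today's squats?", "bct_tags": [13]},
    {"id": "greeting-3", "text": "Great that you made time for your exercises today.", "bct_tags": [13]},
    {"id": "greeting-4", "text": "Hello! Let's get moving.", "bct_tags": [13]}
  ],
  "reminder": [
    {"id": "reminder-1", "text": "Friendly reminder: your squat session is due today.", "bct_tags": [2, 13]},
    {"id": "reminder-2", "text": "Don't forget your squats - three sessions this week keep you on track.", "bct_tags": [2, 13]},
    {"id": "reminder-3", "text": "Time for your exercises! A short session now beats a skipped one.", "bct_tags": [2, 13]}
  ],
  "psychoeducation": [
    {"id": "psychoeducation-1", "text": "Regular strength exercise is linked to better sleep quality.", "bct_tags": [15, 20]},
    {"id": "psychoeducation-2", "text": "Consistent practice can reduce your degree of pain over time.", "bct_tags": [15, 20]},
    {"id": "psychoeducation-3", "text": "Squats strengthen the muscles that protect your knees and back.", "bct_tags": [15, 20]}
  ],
  "progress": [
    {"id": "progress-1", "text": "You have completed %d sessions so far - keep it up!", "bct_tags": [19]},
    {"id": "progress-2", "text": "Nice progress: %d sessions done already.", "bct_tags": [19]},
    {"id": "progress-3", "text": "Session number %d is in the books. Well done!", "bct_tags": [19]}
  ],
  "cue_depth": [
    {"id": "cue-depth-1", "text": "A little bit lower.", "bct_tags": [19, 21]}
  ],
  "cue_tempo_fast": [
    {"id": "cue-tempo-fast-1", "text": "A bit slower, keep the movement controlled.", "bct_tags": [19, 21]}
  ],
  "cue_tempo_slow": [
    {"id": "cue-tempo-slow-1", "text": "A bit faster, keep a steady rhythm.", "bct_tags": [19, 21]}
  ],
  "cue_dev_left": [
    {"id": "cue-dev-left-1", "text": "You are drifting to the left - move back over your footprints.", "bct_tags": [19, 21]}
  ],
  "cue_dev_right": [
    {"id": "cue-dev-right-1", "text": "You are drifting to the right - move back over your footprints.", "bct_tags": [19, 21]}
  ],
  "cue_dev_front": [
    {"id": "cue-dev-front-1", "text": "You are leaning forward - center yourself over your footprints.", "bct_tags": [19, 21]}
  ],
  "cue_dev_back": [
    {"id": "cue-dev-back-1", "text": "You are leaning backward - center yourself over your footprints.", "bct_tags": [19, 21]}
  ],
  "countdown": [
    {"id": "countdown-1", "text": "Only %s more!", "bct_tags": [12, 15]}
  ],
  "set_complete": [
    {"id": "set-complete-1", "text": "One! Great! You already finished set %d, take a quick break and then let's start with set %d of squats.", "bct_tags": [12, 13, 15]}
  ],
  "session_complete": [
    {"id": "session-complete-1", "text": "One! Fantastic, that was the whole session. See you next time!", "bct_tags": [12, 13, 15]}
  ]
}
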