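{
  "barriers": [
    {
      "id": "c1",
      "when": "current",
      "text": "Bad weather (rain or snow)"
    },
    {
      "id": "c2",
      "when": "current",
      "text": "Too busy at work"
    },
    {
      "id": "c3",
      "when": "current",
      "text": "Feeling tired after work"
    },
    {
      "id": "c4",
      "when": "current",
      "text": "No time in the daily schedule"
    },
    {
      "id": "c5",
      "when": "current",
      "text": "Low motivation to walk"
    },
    {
      "id": "c6",
      "when": "current",
      "text": "Foot, knee, or back pain"
    },
    {
      "id": "c7",
      "when": "current",
      "text": "No one to walk with"
    },
    {
      "id": "c8",
      "when": "current",
      "text": "Walking feels boring"
    },
    {
      "id": "f1",
      "when": "future",
      "text": "Year-end and New Year holidays will disrupt the routine"
    },
    {
      "id": "f2",
      "when": "future",
      "text": "Winter cold will make walking unpleasant"
    },
    {
      "id": "f3",
      "when": "future",
      "text": "A coming busy season at work"
    },
    {
      "id": "f4",
      "when": "future",
      "text": "Travel or business trips"
    },
    {
      "id": "f5",
      "when": "future",
      "text": "Possible illness or injury"
    },
    {
      "id": "f6",
      "when": "future",
      "text": "Losing interest once the novelty wears off"
    }
  ],
  "solutions": [
    {
      "barrier_id": "c1",
      "solution_id": "c1_s1",
      "text": "Walk indoors (shopping mall, station concourse)"
    },
    {
      "barrier_id": "c1",
      "solution_id": "c1_s2",
      "text": "Keep an umbrella and walking shoes at work"
    },
    {
      "barrier_id": "c1",
      "solution_id": "c1_s3",
      "text": "Use a stair circuit at home"
    },
    {
      "barrier_id": "c2",
      "solution_id": "c2_s1",
      "text": "Split walking into several 5-minute bouts"
    },
    {
      "barrier_id": "c2",
      "solution_id": "c2_s2",
      "text": "Walk during phone meetings"
    },
    {
      "barrier_id": "c3",
      "solution_id": "c3_s1",
      "text": "Walk right after leaving work, before sitting down"
    },
    {
      "barrier_id": "c3",
      "solution_id": "c3_s2",
      "text": "Choose a shorter but brisker route"
    },
    {
      "barrier_id": "c3",
      "solution_id": "c3_s3",
      "text": "Go to bed earlier to recover"
    },
    {
      "barrier_id": "c4",
      "solution_id": "c4_s1",
      "text": "Attach walking to an existing habit such as commuting"
    },
    {
      "barrier_id": "c4",
      "solution_id": "c4_s2",
      "text": "Get off one stop early on the way home"
    },
    {
      "barrier_id": "c5",
      "solution_id": "c5_s1",
      "text": "Set a smaller goal for a few days and rebuild momentum"
    },
    {
      "barrier_id": "c5",
      "solution_id": "c5_s2",
      "text": "Listen to music or podcasts while walking"
    },
    {
      "barrier_id": "c5",
      "solution_id": "c5_s3",
      "text": "Reward yourself after a walking streak"
    },
    {
      "barrier_id": "c6",
      "solution_id": "c6_s1",
      "text": "Ask a professional about footwear and insoles"
    },
    {
      "barrier_id": "c6",
      "solution_id": "c6_s2",
      "text": "Switch to shorter, more frequent walks"
    },
    {
      "barrier_id": "c6",
      "solution_id": "c6_s3",
      "text": "Warm up and stretch before walking"
    },
    {
      "barrier_id": "c7",
      "solution_id": "c7_s1",
      "text": "Join a local walking group"
    },
    {
      "barrier_id": "c7",
      "solution_id": "c7_s2",
      "text": "Invite a colleague to a lunchtime walk"
    },
    {
      "barrier_id": "c8",
      "solution_id": "c8_s1",
      "text": "Change the route or direction every week"
    },
    {
      "barrier_id": "c8",
      "solution_id": "c8_s2",
      "text": "Track scenery photos along the walk"
    },
    {
      "barrier_id": "f1",
      "solution_id": "f1_s1",
      "text": "Plan family walks to shrines or sales events"
    },
    {
      "barrier_id": "f1",
      "solution_id": "f1_s2",
      "text": "Keep the morning walk fixed even on holidays"
    },
    {
      "barrier_id": "f2",
      "solution_id": "f2_s1",
      "text": "Prepare warm clothing in advance"
    },
    {
      "barrier_id": "f2",
      "solution_id": "f2_s2",
      "text": "Shift walks to the warmest part of the day"
    },
    {
      "barrier_id": "f2",
      "solution_id": "f2_s3",
      "text": "Walk indoors on the coldest days"
    },
    {
      "barrier_id": "f3",
      "solution_id": "f3_s1",
      "text": "Agree with yourself on a minimum daily walk"
    },
    {
      "barrier_id": "f3",
      "solution_id": "f3_s2",
      "text": "Schedule walks in the calendar like meetings"
    },
    {
      "barrier_id": "f4",
      "solution_id": "f4_s1",
      "text": "Pack walking shoes when traveling"
    },
    {
      "barrier_id": "f4",
      "solution_id": "f4_s2",
      "text": "Explore the destination on foot"
    },
    {
      "barrier_id": "f5",
      "solution_id": "f5_s1",
      "text": "Have a low-intensity fallback routine"
    },
    {
      "barrier_id": "f5",
      "solution_id": "f5_s2",
      "text": "Resume gradually with reduced goals"
    },
    {
      "barrier_id": "f6",
      "solution_id": "f6_s1",
      "text": "Review progress graphs monthly"
    },
    {
      "barrier_id": "f6",
      "solution_id": "f6_s2",
      "text": "Set a seasonal event goal such as a charity walk"
    }
  ]
}
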