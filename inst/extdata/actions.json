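{
  "actions": [
    {
      "id": 1,
      "text": "Get off the bus or train one stop early and walk"
    },
    {
      "id": 2,
      "text": "Take the stairs instead of the elevator or escalator"
    },
    {
      "id": 3,
      "text": "Walk to a shop a little farther away"
    },
    {
      "id": 4,
      "text": "Take a 10-minute walk during your lunch break"
    },
    {
      "id": 5,
      "text": "Park at the far end of the parking area"
    },
    {
      "id": 6,
      "text": "Walk while talking on the phone"
    },
    {
      "id": 7,
      "text": "Stand up and walk around once every hour at work"
    },
    {
      "id": 8,
      "text": "Walk with a family member, friend, or pet after dinner"
    },
    {
      "id": 9,
      "text": "Choose a walking route with pleasant scenery"
    },
    {
      "id": 10,
      "text": "Do errands on foot instead of online or by car"
    },
    {
      "id": 11,
      "text": "Walk briskly for 10 minutes in the morning"
    },
    {
      "id": 12,
      "text": "Use part of your commute as a walking course"
    }
  ]
}
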