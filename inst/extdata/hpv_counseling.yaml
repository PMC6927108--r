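title: HPV vaccine counseling session
goals:
  - goal: Acclimate
    tasks:
      - kind: salutation
        greeting: "Hello! I'm glad you could make time today. How are you?"
        introduction: >-
          I am a counseling assistant, and today I'd like to talk with you
          about the HPV vaccine.
      - kind: initiate_discussion
        disclaimer: >-
          A quick note before we start: I may not be able to address every
          concern, so please bring anything I cannot answer to your health
          care provider.
        overview: >-
          We'll go over what the HPV vaccine does, how well it works, and
          what side effects to expect.
        topic_options:
          - benefits of the vaccine
          - how effective it is
          - possible side effects
      - kind: interview_participant
        interview_questions:
          - "Before we begin, how has your day been going?"
  - goal: Communicate Benefit
    tasks:
      - kind: transition_to_topic
        transition: "Let's start with what the vaccine protects against."
      - kind: discuss_health_topic
        health_items:
          - >-
            The HPV vaccine protects against the types of HPV that most
            often cause cervical, throat, and other cancers.
          - >-
            Vaccination is recommended for preteens so protection is in
            place long before any exposure to the virus.
        answers:
          "who should get the vaccine": >-
            It is routinely recommended at ages 11 to 12, and can be given
            from age 9 through 26.
      - kind: question_answering
        answers:
          "who should get the vaccine": >-
            It is routinely recommended at ages 11 to 12, and can be given
            from age 9 through 26.
  - goal: Communicate Effectiveness
    tasks:
      - kind: transition_to_topic
        transition: "Next, let's talk about how well the vaccine works."
      - kind: discuss_health_topic
        health_items:
          - >-
            In clinical studies the vaccine prevented nearly all infections
            with the HPV types it covers.
        answers:
          "how long does protection last": >-
            Protection has remained strong for more than ten years in
            follow-up studies, with no sign of weakening.
      - kind: question_answering
        answers:
          "how long does protection last": >-
            Protection has remained strong for more than ten years in
            follow-up studies, with no sign of weakening.
  - goal: Communicate Harms
    tasks:
      - kind: transition_to_topic
        transition: "Now a word about side effects."
      - kind: discuss_health_topic
        health_items:
          - >-
            The HPV vaccine might cause some minor discomfort and pain or
            soreness at the injection site.
        answers:
          "are there serious side effects": >-
            Serious side effects are very rare; soreness, redness, or a
            mild fever are the most common reactions.
      - kind: question_answering
        answers:
          "are there serious side effects": >-
            Serious side effects are very rare; soreness, redness, or a
            mild fever are the most common reactions.
  - goal: Communicate Uncertainty
    tasks:
      - kind: transition_to_topic
        transition: "Let me also be clear about what is still being studied."
      - kind: discuss_health_topic
        health_items:
          - >-
            Researchers continue to monitor how long immunity lasts and
            whether a booster will ever be needed.
  - goal: Pursuit Before Exit
    tasks:
      - kind: transition_to_topic
        transition: >-
          I hear your hesitation. May I share one more point before we
          finish? Many families find it helpful.
  - goal: Conclude
    tasks:
      - kind: valediction
        farewell: >-
          That's everything I had for today. Thank you for talking with me.
          Goodbye!
        concluding_farewell: >-
          Take care, and please follow up with your provider about the HPV
          vaccine. Goodbye.
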