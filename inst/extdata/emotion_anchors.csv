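name,valence,arousal
joy,7.8,7.0
passion,7.4,7.8
surprise,6.6,7.4
mania,6.2,8.2
confidence,7.2,6.0
hope,6.6,5.4
concentration,5.4,5.2
relaxation,7.0,2.8
intimacy,7.6,3.6
trust,6.8,4.2
gratitude,7.2,4.4
anger,2.2,7.8
fear,2.6,7.4
anxiety,3.2,6.8
disgust,2.8,6.2
pain,2.4,5.8
insecurity,3.4,5.6
sadness,2.4,3.0
despair,1.8,3.6
tiredness,3.6,2.4
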