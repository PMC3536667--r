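name,met
running,9.8
jogging,7.0
swimming,6.0
cycling,7.5
soccer,7.0
tennis,7.3
basketball,6.5
volleyball,4.0
badminton,5.5
fitness,5.0
dancing,5.0
walking,4.3
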