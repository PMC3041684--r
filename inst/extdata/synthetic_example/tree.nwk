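((sp04:1.576830459,sp08:1.576830459)1.00:5.323169541,(((sp07:3.27282974,sp03:3.27282974)0.99:2.523025449,((sp09:0.07648029584,sp01:0.07648029584)0.99:1.471030233,sp06:1.547510528)0.52:4.24834466)1.00:0.296655641,(sp02:2.722794081,(sp05:0.255279031,sp10:0.255279031)0.99:2.46751505)1.00:3.369716748)0.86:0.8074891706)0.98;
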