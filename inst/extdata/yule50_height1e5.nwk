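((((s25:3936.052351,s47:3936.052351):4090.177067,s20:8026.229418):29000.27913,(((s49:13913.1675,((s29:1232.648835,s3:1232.648835):11091.3545,(s7:6547.856619,s30:6547.856619):5776.146715):1589.164167):7251.653176,(s26:2841.206921,s8:2841.206921):18323.61376):15346.425,(((s43:7333.677324,(s45:443.9501114,s5:443.9501114):6889.727213):15016.90244,s16:22350.57977):8487.981253,(s27:5456.286938,s15:5456.286938):25382.27408):5672.68466):515.2628681):62973.49145,(((s32:62186.41286,(((s4:2768.973381,s22:2768.973381):23385.00443,((s48:5429.790329,s39:5429.790329):6522.230925,(s50:6102.485487,(s37:1232.025697,s17:1232.025697):4870.45979):5849.535767):14201.95655):32799.17999,((s1:22305.14935,(s35:5519.588456,s41:5519.588456):16785.5609):17117.30036,((s9:27857.84034,((s33:20621.1416,s42:20621.1416):4894.667775,(s46:20597.18913,(s23:611.3155387,s21:611.3155387):19985.87359):4918.620243):2342.030969):1464.789373,((s2:11220.6316,s19:11220.6316):12726.0272,(((s28:1711.41154,s38:1711.41154):8832.654572,s36:10544.06611):8118.786576,s18:18662.85269):5283.806111):5375.970914):10099.81999):19530.70809):3233.255064):10057.01373,(s13:6853.383519,s11:6853.383519):65390.04307):17842.23131,((s14:40148.00839,((s34:12901.19114,s6:12901.19114):11576.4514,(s10:23460.92412,(s24:18540.65276,((s31:4111.975622,s12:4111.975622):2100.317435,s44:6212.293057):12328.35971):4920.271361):1016.718422):15670.36584):12751.80023,s40:52899.80862):37185.84928):9914.342098);
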