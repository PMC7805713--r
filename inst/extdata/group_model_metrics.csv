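classifier,train_accuracy,train_loss,val_accuracy,val_loss,test_accuracy
TD,0.6733,0.8472,0.6800,0.8263,0.6803
ASD,0.6389,0.9320,0.6512,0.8858,0.6524
Combined,0.6733,0.8472,0.6800,0.8263,0.6803
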