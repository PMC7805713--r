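id,group,interaction_length_s,n_datapoints,train_accuracy,train_loss,val_accuracy,val_loss,test_accuracy
1,TD,315,9444,0.8101,0.5028,0.7790,0.6681,0.7946
2,TD,519,15357,0.6499,0.7278,0.6398,0.7797,0.6393
3,TD,540,16412,0.6703,0.8723,0.6407,1.0095,0.6526
4,TD,658,10933,0.8302,0.4189,0.8131,0.4923,0.8240
5,TD,797,22996,0.9255,0.1903,0.9198,0.2484,0.9159
6,TD,696,9300,0.9200,0.2850,0.8925,0.3856,0.9124
7,TD,316,9388,0.7821,0.5423,0.7417,0.7946,0.7338
8,TD,457,13725,0.7561,0.6065,0.7418,0.6796,0.7483
9,TD,574,10463,0.6671,0.8486,0.6535,0.9333,0.6364
10,TD,780,16627,0.9104,0.2253,0.8831,0.3907,0.8698
11,TD,726,12726,0.8390,0.3843,0.8303,0.4039,0.8283
12,TD,685,9723,0.8118,0.5162,0.7715,0.6980,0.7720
13,TD,540,12879,0.8084,0.4296,0.7812,0.5858,0.7702
14,ASD,517,15502,0.8163,0.4417,0.7952,0.5621,0.7907
15,ASD,578,14624,0.9204,0.2276,0.8923,0.3390,0.9108
16,ASD,679,15950,0.6810,0.7582,0.6501,0.9095,0.6398
17,ASD,610,16401,0.8306,0.3946,0.8232,0.4923,0.8366
18,ASD,1058,30508,0.7822,0.5467,0.7759,0.6323,0.7812
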