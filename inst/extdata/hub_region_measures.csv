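region,measure,group,mean,sd,n
Frontal sup L,strength,control,26243.86,6664.45,22
Frontal sup L,strength,mTBI,24337.67,6797.60,12
Frontal sup L,strength,msTBI,16928.50,6436.89,10
Frontal sup L,efficiency,control,0.043,0.008,22
Frontal sup L,efficiency,mTBI,0.033,0.006,12
Frontal sup L,efficiency,msTBI,0.034,0.006,10
Frontal sup L,clustering,control,0.024,0.005,22
Frontal sup L,clustering,mTBI,0.021,0.005,12
Frontal sup L,clustering,msTBI,0.017,0.004,10
Frontal sup R,strength,control,29299.55,5302.82,22
Frontal sup R,strength,mTBI,27710.33,6163.02,12
Frontal sup R,strength,msTBI,21453.80,5685.43,10
Frontal sup R,efficiency,control,0.052,0.012,22
Frontal sup R,efficiency,mTBI,0.027,0.009,12
Frontal sup R,efficiency,msTBI,0.025,0.006,10
Frontal sup R,clustering,control,0.024,0.005,22
Frontal sup R,clustering,mTBI,0.023,0.005,12
Frontal sup R,clustering,msTBI,0.019,0.007,10
Frontal sup medial L,strength,control,20871.64,4654.06,22
Frontal sup medial L,strength,mTBI,19552.92,6189.66,12
Frontal sup medial L,strength,msTBI,13153.00,5287.82,10
Frontal sup medial L,efficiency,control,0.039,0.010,22
Frontal sup medial L,efficiency,mTBI,0.033,0.009,12
Frontal sup medial L,efficiency,msTBI,0.032,0.006,10
Frontal sup medial L,clustering,control,0.025,0.008,22
Frontal sup medial L,clustering,mTBI,0.022,0.005,12
Frontal sup medial L,clustering,msTBI,0.017,0.008,10
Occipital sup L,strength,control,16143.32,4365.34,22
Occipital sup L,strength,mTBI,16563.33,2893.53,12
Occipital sup L,strength,msTBI,15956.70,4191.42,10
Occipital sup L,efficiency,control,0.027,0.008,22
Occipital sup L,efficiency,mTBI,0.015,0.008,12
Occipital sup L,efficiency,msTBI,0.018,0.004,10
Occipital sup L,clustering,control,0.025,0.007,22
Occipital sup L,clustering,mTBI,0.023,0.009,12
Occipital sup L,clustering,msTBI,0.026,0.007,10
Occipital mid L,strength,control,18496.32,6467.73,22
Occipital mid L,strength,mTBI,16038.92,4914.06,12
Occipital mid L,strength,msTBI,16308.10,5152.09,10
Occipital mid L,efficiency,control,0.042,0.007,22
Occipital mid L,efficiency,mTBI,0.039,0.004,12
Occipital mid L,efficiency,msTBI,0.035,0.004,10
Occipital mid L,clustering,control,0.021,0.005,22
Occipital mid L,clustering,mTBI,0.017,0.006,12
Occipital mid L,clustering,msTBI,0.018,0.006,10
Parietal sup L,strength,control,14296.23,6023.34,22
Parietal sup L,strength,mTBI,13607.17,4153.52,12
Parietal sup L,strength,msTBI,12076.90,5132.47,10
Parietal sup L,efficiency,control,0.021,0.009,22
Parietal sup L,efficiency,mTBI,0.031,0.007,12
Parietal sup L,efficiency,msTBI,0.028,0.005,10
Parietal sup L,clustering,control,0.019,0.006,22
Parietal sup L,clustering,mTBI,0.016,0.004,12
Parietal sup L,clustering,msTBI,0.016,0.005,10
Precuneus L,strength,control,23719.91,8218.06,22
Precuneus L,strength,mTBI,23692.33,7914.93,12
Precuneus L,strength,msTBI,19523.70,8711.02,10
Precuneus L,efficiency,control,0.044,0.015,22
Precuneus L,efficiency,mTBI,0.033,0.010,12
Precuneus L,efficiency,msTBI,0.035,0.004,10
Precuneus L,clustering,control,0.026,0.009,22
Precuneus L,clustering,mTBI,0.022,0.008,12
Precuneus L,clustering,msTBI,0.021,0.006,10
Precuneus R,strength,control,26970.68,7471.84,22
Precuneus R,strength,mTBI,24887.42,8190.68,12
Precuneus R,strength,msTBI,23395.30,7205.23,10
Precuneus R,efficiency,control,0.043,0.014,22
Precuneus R,efficiency,mTBI,0.037,0.008,12
Precuneus R,efficiency,msTBI,0.038,0.009,10
Precuneus R,clustering,control,0.028,0.009,22
Precuneus R,clustering,mTBI,0.027,0.011,12
Precuneus R,clustering,msTBI,0.025,0.007,10
Putamen L,strength,control,32325.14,7668.55,22
Putamen L,strength,mTBI,31230.25,8074.44,12
Putamen L,strength,msTBI,26900.90,6459.47,10
Putamen L,efficiency,control,0.047,0.006,22
Putamen L,efficiency,mTBI,0.049,0.006,12
Putamen L,efficiency,msTBI,0.051,0.005,10
Putamen L,clustering,control,0.023,0.005,22
Putamen L,clustering,mTBI,0.021,0.005,12
Putamen L,clustering,msTBI,0.018,0.007,10
Putamen R,strength,control,28512.32,6951.38,22
Putamen R,strength,mTBI,28347.50,8210.44,12
Putamen R,strength,msTBI,23589.30,5439.57,10
Putamen R,efficiency,control,0.041,0.006,22
Putamen R,efficiency,mTBI,0.046,0.004,12
Putamen R,efficiency,msTBI,0.047,0.005,10
Putamen R,clustering,control,0.018,0.004,22
Putamen R,clustering,mTBI,0.019,0.005,12
Putamen R,clustering,msTBI,0.016,0.004,10
Thalamus R,strength,control,16018.23,4830.37,22
Thalamus R,strength,mTBI,17182.17,6444.93,12
Thalamus R,strength,msTBI,13045.70,2766.95,10
Thalamus R,efficiency,control,0.027,0.007,22
Thalamus R,efficiency,mTBI,0.024,0.003,12
Thalamus R,efficiency,msTBI,0.028,0.010,10
Thalamus R,clustering,control,0.017,0.005,22
Thalamus R,clustering,mTBI,0.017,0.004,12
Thalamus R,clustering,msTBI,0.018,0.009,10
Temporal mid L,strength,control,13183.50,2502.74,22
Temporal mid L,strength,mTBI,13487.50,3263.81,12
Temporal mid L,strength,msTBI,11656.10,2847.73,10
Temporal mid L,efficiency,control,0.026,0.007,22
Temporal mid L,efficiency,mTBI,0.020,0.004,12
Temporal mid L,efficiency,msTBI,0.024,0.007,10
Temporal mid L,clustering,control,0.019,0.005,22
Temporal mid L,clustering,mTBI,0.019,0.008,12
Temporal mid L,clustering,msTBI,0.015,0.005,10
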